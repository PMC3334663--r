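#' Longitudinal paired-limb cohort design
#'
#' Specifies the group means and standard deviations of each morphometric
#' parameter per compartment and timepoint for the MIA-injected and control
#' limbs, the number of animals and the within-animal (inter-limb)
#' correlation. The default correlation of 0.7 is a declared assumption of
#' the simulator, not an observed value.
#'
#' @param means data.frame with columns `parameter`, `compartment`, `week`,
#'   `mia_mean`, `mia_sd`, `ctl_mean`, `ctl_sd`.
#' @param n_animals number of animals (each contributes both limbs).
#' @param correlation within-animal correlation in `[0, 1)` shared across a
#'   parameter's repeated measurements.
#' @param seed integer seed used by [simulate_cohort()].
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(means, n_animals = 12L, correlation = 0.7,
                          seed = 1L) {
  req <- c("parameter", "compartment", "week", "mia_mean", "mia_sd",
           "ctl_mean", "ctl_sd")
  if (!is.data.frame(means) || !all(req %in% names(means)))
    stop("means must be a data.frame with columns ",
         paste(req, collapse = ", "))
  if (any(means$mia_sd < 0) || any(means$ctl_sd < 0))
    stop("standard deviations must be >= 0")
  if (any(means$mia_mean <= 0) || any(means$ctl_mean <= 0))
    stop("means must be positive for length/volume parameters")
  if (!is.numeric(correlation) || correlation < 0 || correlation >= 1)
    stop("correlation must lie in [0, 1)")
  if (n_animals < 1L) stop("n_animals must be >= 1")
  if (anyDuplicated(means[, c("parameter", "compartment", "week")]))
    stop("duplicate parameter x compartment x week rows in the design")
  structure(list(means = means, n_animals = as.integer(n_animals),
                 timepoints = sort(unique(means$week)),
                 correlation = correlation, seed = as.integer(seed)),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "<cohort_design> %d animals, weeks %s, correlation %.2f, %d parameter cells\n",
    x$n_animals, paste(x$timepoints, collapse = "/"), x$correlation,
    nrow(x$means)))
  invisible(x)
}

#' Published study design: 12-animal MIA cohort
#'
#' The per-timepoint group means and SDs of the trabecular parameters (BV,
#' BV/TV, Tb.Th, Tb.N, Tb.Sp; medial/lateral/total) and the subchondral plate
#' thickness, as printed for the 12-rat low-dose MIA study at 2, 6 and 10
#' weeks. Plate porosity is not included: the source tables print only its
#' percent differences, not group means.
#'
#' @return A data.frame usable as the `means` argument of [cohort_design()].
#' @export
mia_table_design <- function() {
  tbl <- function(parameter, week, med, lat, tot) {
    data.frame(parameter = parameter,
               compartment = c("medial", "lateral", "total"),
               week = week,
               mia_mean = c(med[1], lat[1], tot[1]),
               mia_sd = c(med[2], lat[2], tot[2]),
               ctl_mean = c(med[3], lat[3], tot[3]),
               ctl_sd = c(med[4], lat[4], tot[4]),
               stringsAsFactors = FALSE)
  }
  rbind(
    tbl("BV", 2, c(613, 97, 745, 118), c(647, 120, 711, 130),
        c(1260, 202, 1456, 239)),
    tbl("BV", 6, c(1177, 211, 993, 214), c(1145, 168, 948, 169),
        c(2322, 341, 1941, 370)),
    tbl("BV", 10, c(1481, 271, 1179, 229), c(1229, 133, 1205, 241),
        c(2710, 326, 2384, 454)),
    tbl("BV/TV", 2, c(16.8, 2.6, 20.4, 3.2), c(15.1, 2.8, 16.7, 3.0),
        c(15.9, 2.5, 18.6, 3.0)),
    tbl("BV/TV", 6, c(32.7, 6.5, 27.5, 6.6), c(27.2, 3.6, 22.2, 3.8),
        c(30.0, 4.2, 24.8, 5.0)),
    tbl("BV/TV", 10, c(39.8, 7.7, 33.6, 7.6), c(29.0, 3.2, 28.2, 6.0),
        c(34.4, 4.8, 30.9, 6.4)),
    tbl("Tb.Th", 2, c(94, 5, 92, 3), c(89, 4, 87, 3), c(91, 4, 90, 3)),
    tbl("Tb.Th", 6, c(124, 11, 100, 9), c(117, 9, 95, 5), c(120, 9, 97, 7)),
    tbl("Tb.Th", 10, c(149, 19, 110, 12), c(128, 17, 105, 8),
        c(138, 18, 108, 10)),
    tbl("Tb.N", 2, c(1.8, 0.3, 2.2, 0.3), c(1.7, 0.3, 1.9, 0.3),
        c(1.7, 0.2, 2.1, 0.3)),
    tbl("Tb.N", 6, c(2.5, 0.5, 2.7, 0.5), c(2.2, 0.3, 2.3, 0.3),
        c(2.3, 0.3, 2.5, 0.4)),
    tbl("Tb.N", 10, c(2.6, 0.5, 3.1, 0.4), c(2.3, 0.3, 2.7, 0.3),
        c(2.5, 0.3, 2.9, 0.4)),
    tbl("Tb.Sp", 2, c(270, 16, 243, 17), c(272, 16, 256, 17),
        c(271, 13, 250, 14)),
    tbl("Tb.Sp", 6, c(240, 19, 203, 24), c(250, 16, 221, 14),
        c(245, 15, 212, 16)),
    tbl("Tb.Sp", 10, c(241, 32, 207, 20), c(258, 17, 223, 15),
        c(245, 22, 215, 15)),
    tbl("Pl.Th", 2, c(114, 7, 105, 7), c(101, 6, 109, 7), c(107, 4, 107, 8)),
    tbl("Pl.Th", 6, c(146, 32, 119, 32), c(130, 17, 120, 26),
        c(138, 23, 118, 26)),
    tbl("Pl.Th", 10, c(181, 27, 175, 31), c(166, 18, 178, 24),
        c(177, 19, 177, 25))
  )
}

#' Simulate a paired-limb longitudinal cohort
#'
#' Draws one record per animal, limb, timepoint, compartment and parameter.
#' Each animal carries a shared Gaussian random effect so that the two limbs
#' (and repeated timepoints) of one animal are correlated at the design
#' correlation while the marginal distribution at every cell matches the
#' design mean and SD:
#' `value = mean + sd * (sqrt(rho) * a_i + sqrt(1 - rho) * e)`.
#'
#' @param design a [cohort_design()].
#' @param seed optional seed overriding the design seed.
#' @return A long-format data.frame of class `longitudinal_dataset` with
#'   columns `animal`, `limb` (`"MIA"`/`"control"`), `week`, `compartment`,
#'   `parameter`, `value`.
#' @export
simulate_cohort <- function(design, seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(seed)) seed <- design$seed
  n <- design$n_animals
  rho <- design$correlation
  m <- design$means
  with_seed(seed, {
    pieces <- vector("list", nrow(m) * 2L)
    keys <- unique(m[, c("parameter", "compartment")])
    out <- list()
    for (r in seq_len(nrow(keys))) {
      par <- keys$parameter[r]; cmp <- keys$compartment[r]
      a_i <- stats::rnorm(n)          # shared animal effect per parameter
      cells <- m[m$parameter == par & m$compartment == cmp, , drop = FALSE]
      for (i in seq_len(nrow(cells))) {
        for (limb in c("MIA", "control")) {
          mu <- if (limb == "MIA") cells$mia_mean[i] else cells$ctl_mean[i]
          sd <- if (limb == "MIA") cells$mia_sd[i] else cells$ctl_sd[i]
          e <- stats::rnorm(n)
          out[[length(out) + 1L]] <- data.frame(
            animal = seq_len(n), limb = limb, week = cells$week[i],
            compartment = cmp, parameter = par,
            value = mu + sd * (sqrt(rho) * a_i + sqrt(1 - rho) * e),
            stringsAsFactors = FALSE)
        }
      }
    }
    ds <- do.call(rbind, out)
    rownames(ds) <- NULL
    class(ds) <- c("longitudinal_dataset", "data.frame")
    attr(ds, "design_seed") <- seed
    ds
  })
}

#' @export
print.longitudinal_dataset <- function(x, ...) {
  cat(sprintf(
    "<longitudinal_dataset> %d records: %d animals, weeks %s, %d parameters\n",
    nrow(x), length(unique(x$animal)),
    paste(sort(unique(x$week)), collapse = "/"),
    length(unique(x$parameter))))
  invisible(x)
}

#' Read/write longitudinal datasets as long-format CSV
#'
#' Columns: `animal`, `limb`, `week`, `compartment`, `parameter`, `value`.
#'
#' @param path CSV path.
#' @return [read_cohort_csv()] returns a `longitudinal_dataset`.
#' @export
read_cohort_csv <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal", "limb", "week", "compartment", "parameter", "value")
  if (!all(req %in% names(ds)))
    stop("cohort CSV must have columns ", paste(req, collapse = ", "))
  if (any(!is.finite(ds$value))) stop("non-finite values in cohort CSV")
  class(ds) <- c("longitudinal_dataset", "data.frame")
  ds
}

#' @rdname read_cohort_csv
#' @param dataset a `longitudinal_dataset`.
#' @export
write_cohort_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}
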