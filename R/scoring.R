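#' Combined macroscopic joint grade
#'
#' Macroscopic cartilage lesions are graded 0-4 per compartment (0 normal
#' appearance ... 4 large erosion with subchondral bone exposure) by each
#' observer for the medial and lateral tibial plateau separately. The
#' per-observer compartment grades are combined (sum by default, giving the
#' 0-8 combined joint scale; mean available) and summarised across
#' observers/animals as mean and SD.
#'
#' @param grades data.frame with columns `observer`, `compartment`
#'   (`"medial"`/`"lateral"`) and `grade` (integers 0-4); an optional
#'   `animal` column separates animals.
#' @param combine `"sum"` (default) or `"mean"` of the two compartments.
#' @return List with `per_observer` (one combined value per observer x
#'   animal), `mean` and `sd`.
#' @export
joint_grade <- function(grades, combine = c("sum", "mean")) {
  combine <- match.arg(combine)
  req <- c("observer", "compartment", "grade")
  if (!is.data.frame(grades) || !all(req %in% names(grades)))
    stop("grades needs columns observer, compartment, grade")
  if (nrow(grades) == 0L) stop("no grades supplied")
  if (!all(grades$grade %in% 0:4))
    stop("macroscopic grades must be integers in 0-4")
  if (!all(grades$compartment %in% c("medial", "lateral")))
    stop("compartment must be 'medial' or 'lateral'")
  if (!"animal" %in% names(grades)) grades$animal <- 1L
  key <- interaction(grades$animal, grades$observer, drop = TRUE)
  per <- vapply(split(grades, key), function(g) {
    if (!all(c("medial", "lateral") %in% g$compartment))
      stop("each observer needs both medial and lateral grades")
    v <- c(g$grade[g$compartment == "medial"][1],
           g$grade[g$compartment == "lateral"][1])
    if (combine == "sum") sum(v) else mean(v)
  }, numeric(1))
  list(per_observer = per, mean = mean(per),
       sd = if (length(per) > 1L) stats::sd(per) else NA_real_)
}

#' OARSI osteoarthritis score
#'
#' The histopathology score is the product of grade (depth of cartilage
#' lesion, 0-6) and stage (extent of involvement, 0-4), ranging 0 (no OA
#' activity) to 24 (highest degradation). Vectorised.
#'
#' @param grade integer(s) in 0-6.
#' @param stage integer(s) in 0-4.
#' @return Score(s) = grade x stage, in 0-24.
#' @export
oarsi <- function(grade, stage) {
  if (any(!grade %in% 0:6)) stop("OARSI grade must be an integer in 0-6")
  if (any(!stage %in% 0:4)) stop("OARSI stage must be an integer in 0-4")
  grade * stage
}
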