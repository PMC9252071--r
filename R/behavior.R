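#' Novel-object-recognition discrimination index
#'
#' `DI = (Tn - Tf) / (Tn + Tf)`, where `Tn` is the time spent exploring
#' the novel object and `Tf` the familiar one (seconds). Animals whose
#' exploration falls below the 8-second criterion are excluded and their
#' DI reported as missing. By default the criterion is read as total
#' exploration (`Tn + Tf < min_exploration_s`); the alternative reading
#' (either object explored less than the criterion) is available as
#' `rule = "per_object"`.
#'
#' @param tn Seconds exploring the novel object (vectorized, `>= 0`).
#' @param tf Seconds exploring the familiar object (same length).
#' @param min_exploration_s Exclusion criterion in seconds (default 8).
#' @param rule `"total"` (default) or `"per_object"`.
#' @return `data.frame` with columns `tn`, `tf`, `di` (in `[-1, 1]`, NA
#'   when excluded) and `excluded`.
#' @examples
#' discrimination_index(c(15, 10, 3), c(5, 10, 4))
#' @export
discrimination_index <- function(tn, tf, min_exploration_s = 8,
                                 rule = c("total", "per_object")) {
  rule <- match.arg(rule)
  if (length(tn) != length(tf)) stop("`tn` and `tf` differ in length")
  tn <- as.numeric(tn); tf <- as.numeric(tf)
  if (anyNA(tn) || anyNA(tf)) stop("exploration times must not be NA")
  if (any(tn < 0) || any(tf < 0)) {
    stop("exploration times must be non-negative")
  }
  total <- tn + tf
  excluded <- if (rule == "total") total < min_exploration_s
              else tn < min_exploration_s | tf < min_exploration_s
  di <- ifelse(!excluded & total > 0, (tn - tf) / total, NA_real_)
  # a zero total always counts as excluded (no exploration at all)
  excluded <- excluded | total == 0
  data.frame(tn = tn, tf = tf, di = di, excluded = excluded)
}
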