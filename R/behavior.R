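#' Sociability index
#'
#' Ratio of the time spent on the stranger-animal side of the three-chamber
#' test to the time spent on the empty side. Undefined (returned as `NA`
#' with a warning) when the empty-side time is zero.
#'
#' @param time_stranger,time_empty Durations in seconds (vectorized,
#'   non-negative).
#' @return Sociability index (unitless).
#' @export
sociability_index <- function(time_stranger, time_empty) {
  if (any(time_stranger < 0) || any(time_empty < 0)) {
    stop("durations must be non-negative")
  }
  si <- ifelse(time_empty > 0, time_stranger / time_empty, NA_real_)
  if (any(is.na(si))) {
    warning("sociability index undefined for zero empty-side time")
  }
  si
}

#' Read a behavioral-trial table
#'
#' @param path TSV with header and columns `animal_id`, `group`,
#'   `time_stranger`, `time_empty`, `grooming`.
#' @return data.frame with an added `si` column.
#' @export
read_behavior_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  required <- c("animal_id", "group", "time_stranger", "time_empty", "grooming")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("behavior table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$si <- sociability_index(df$time_stranger, df$time_empty)
  df
}

#' Two-group comparison with a normality gate
#'
#' Runs a Shapiro-Wilk normality test per group, then the standard
#' pooled-variance unpaired t-test (`df = n1 + n2 - 2`); Welch's correction
#' is available behind the `welch` flag. Non-normal data (either Shapiro
#' p <= 0.05) triggers a warning, not an automatic nonparametric fallback.
#' Degenerate inputs (zero variance in both groups) give `t = 0`, `p = 1`
#' when the means agree and are flagged.
#'
#' @param values_a,values_b Numeric vectors with at least 3 values each.
#' @param welch Use Welch's unequal-variance t-test instead of the
#'   pooled-variance test.
#' @return List: `shapiro_p` (length-2 vector, `NA` when a group is
#'   constant), `t`, `df`, `p`, `flag` (`ok` or `degenerate`).
#' @export
two_group_test <- function(values_a, values_b, welch = FALSE) {
  if (length(values_a) < 3 || length(values_b) < 3) {
    stop("at least 3 values per group are required")
  }
  sw <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  shapiro_p <- c(a = sw(values_a), b = sw(values_b))
  if (any(!is.na(shapiro_p) & shapiro_p <= 0.05)) {
    warning("Shapiro-Wilk p <= 0.05: data may violate the normality ",
            "assumption of the t-test")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    diff <- mean(values_a) - mean(values_b)
    if (diff == 0) {
      return(list(shapiro_p = shapiro_p, t = 0,
                  df = length(values_a) + length(values_b) - 2, p = 1,
                  flag = "degenerate"))
    }
    return(list(shapiro_p = shapiro_p, t = sign(diff) * Inf,
                df = length(values_a) + length(values_b) - 2, p = 0,
                flag = "degenerate"))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = !welch)
  list(shapiro_p = shapiro_p,
       t = unname(tt$statistic),
       df = unname(tt$parameter),
       p = tt$p.value,
       flag = "ok")
}

#' Per-measure behavioral report for a two-group trial table
#'
#' Applies [two_group_test()] to each behavioral measure (stranger time,
#' empty time, grooming, sociability index) between the two groups.
#'
#' @param behavior data.frame as returned by [read_behavior_tsv()] or
#'   [simulate_behavior()].
#' @param control,case Group labels.
#' @param welch Passed to [two_group_test()].
#' @return data.frame with one row per measure: `measure`, `mean_control`,
#'   `mean_case`, `t`, `df`, `p`.
#' @export
behavior_report <- function(behavior, control = "control", case = "case",
                            welch = FALSE) {
  if (!("si" %in% names(behavior))) {
    behavior$si <- sociability_index(behavior$time_stranger,
                                     behavior$time_empty)
  }
  measures <- c("time_stranger", "time_empty", "grooming", "si")
  rows <- lapply(measures, function(mv) {
    a <- behavior[[mv]][behavior$group == control]
    b <- behavior[[mv]][behavior$group == case]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    res <- two_group_test(a, b, welch = welch)
    data.frame(measure = mv, mean_control = mean(a), mean_case = mean(b),
               t = res$t, df = res$df, p = res$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
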