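#' Duration distribution summaries per light condition
#'
#' Empirical CDFs, histograms and the short-seizure fraction
#' (duration < 5 s) for the light-on and light-off rows of a seizure
#' duration table.
#'
#' @param table data.frame with columns `animal`, `condition`
#'   (`"light_on"` / `"light_off"`) and `duration_from_trigger` (s).
#' @param short_cutoff s (default 5).
#' @param breaks passed to [hist()]-style binning (number or vector).
#' @return named list per condition: `ecdf` (right-continuous step
#'   function reaching 1), `hist` (list with `breaks`, `counts`),
#'   `short_fraction`, `n`.
#' @export
ecdf_and_histogram <- function(table, short_cutoff = 5, breaks = 20) {
  conds <- unique(table$condition)
  out <- lapply(conds, function(cc) {
    d <- table$duration_from_trigger[table$condition == cc]
    if (length(d) == 0) stop("empty condition: ", cc)
    br <- if (length(breaks) == 1)
      seq(min(d), max(d), length.out = breaks + 1) else breaks
    idx <- findInterval(d, br, rightmost.closed = TRUE, all.inside = TRUE)
    list(ecdf = stats::ecdf(d),
         hist = list(breaks = br, counts = tabulate(idx, length(br) - 1)),
         short_fraction = mean(d < short_cutoff),
         n = length(d))
  })
  stats::setNames(out, conds)
}

#' Per-animal normalized seizure duration
#'
#' For each animal, the mean light-on duration divided by the mean
#' light-off duration, times 100 (percent); the group summary is the mean
#' and s.e.m. of these per-animal percentages across animals — never
#' across seizures. Animals missing a condition, or with a zero off-mean,
#' are excluded with a warning. The ratio is invariant to rescaling all
#' of one animal's durations.
#'
#' @param table as in [ecdf_and_histogram()].
#' @return list of class `"effect_summary"`: `per_animal` (data.frame
#'   `animal, pct, n_on, n_off`), `mean_pct`, `sem_pct`, `n_animals`,
#'   `n_seizures_on`, `n_seizures_off`.
#' @export
normalized_duration <- function(table) {
  animals <- unique(table$animal)
  rows <- lapply(animals, function(a) {
    on <- table$duration_from_trigger[table$animal == a &
                                      table$condition == "light_on"]
    off <- table$duration_from_trigger[table$animal == a &
                                       table$condition == "light_off"]
    if (length(on) == 0 || length(off) == 0) {
      warning("animal ", a, " missing a condition; excluded")
      return(NULL)
    }
    if (mean(off) == 0) {
      warning("animal ", a, " has zero light-off mean; excluded")
      return(NULL)
    }
    data.frame(animal = a, pct = 100 * mean(on) / mean(off),
               n_on = length(on), n_off = length(off))
  })
  per <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(per) || nrow(per) == 0) stop("no animal has both conditions")
  structure(list(per_animal = per,
                 mean_pct = mean(per$pct),
                 sem_pct = if (nrow(per) > 1)
                   stats::sd(per$pct) / sqrt(nrow(per)) else NA_real_,
                 n_animals = nrow(per),
                 n_seizures_on = sum(per$n_on),
                 n_seizures_off = sum(per$n_off)),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("normalized seizure duration: %.1f +/- %.1f%% (s.e.m.), %d animals, %d on / %d off seizures\n",
              x$mean_pct, x$sem_pct, x$n_animals,
              x$n_seizures_on, x$n_seizures_off))
  invisible(x)
}

#' Mixed-effect model for light condition
#'
#' Two-level model of seizure duration: fixed effect of light condition
#' with a random intercept per animal, fitted by REML (lme4), with the
#' condition F test computed by Satterthwaite's method (lmerTest). This
#' is the minimal structure for thousands of seizures nested in a few
#' animals; singular fits on degenerate data are reported in the result,
#' not silenced.
#'
#' @param table as in [ecdf_and_histogram()].
#' @return list of class `"model_result"`: `F`, `df1`, `df2`, `p`,
#'   `effect` (light-on minus light-off, s), `singular`, `model`.
#' @export
mixed_model_duration <- function(table) {
  if (length(unique(table$animal)) < 2)
    stop("need >= 2 animals for the mixed model")
  if (length(unique(table$condition)) < 2)
    stop("need both light conditions")
  d <- data.frame(duration = table$duration_from_trigger,
                  condition = factor(table$condition,
                                     levels = c("light_off", "light_on")),
                  animal = factor(table$animal))
  fit <- suppressMessages(lmerTest::lmer(
    duration ~ condition + (1 | animal), data = d, REML = TRUE))
  a <- stats::anova(fit)
  structure(list(F = a[1, "F value"], df1 = a[1, "NumDF"],
                 df2 = a[1, "DenDF"], p = a[1, "Pr(>F)"],
                 effect = unname(lme4::fixef(fit)["conditionlight_on"]),
                 singular = lme4::isSingular(fit),
                 model = fit),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("condition effect %.3f s; F(%d, %.0f) = %.2f, p = %.3g%s\n",
              x$effect, x$df1, x$df2, x$F, x$p,
              if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' Between-group test on per-animal normalized durations
#'
#' Two-sample two-tailed t test comparing the per-animal normalized
#' duration percentages of the opsin group against the control group
#' (equal-variance by default; set `var_equal = FALSE` for Welch).
#'
#' @param opsin,control [normalized_duration()] summaries (or numeric
#'   vectors of per-animal percentages).
#' @param var_equal logical.
#' @return list `(t, df, p)`.
#' @export
group_ttest <- function(opsin, control, var_equal = TRUE) {
  x <- if (inherits(opsin, "effect_summary")) opsin$per_animal$pct else opsin
  y <- if (inherits(control, "effect_summary")) control$per_animal$pct else control
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 animals per group")
  tt <- stats::t.test(x, y, var.equal = var_equal, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
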