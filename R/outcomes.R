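#' Percent change from an animal's average baseline binge size
#'
#' Session intakes are normalized per animal as
#' `100 * (intake - baseline) / baseline`, which removes the known
#' between-animal variation in absolute binge size before any thresholding.
#'
#' @param intake Session intake(s), kcal.
#' @param baseline_mean The animal's mean baseline intake, kcal (must be
#'   positive).
#' @return Percent change(s) from baseline.
#' @examples
#' percent_change_from_baseline(7.4, 10)  # -26
#' @export
percent_change_from_baseline <- function(intake, baseline_mean) {
  stop_if_not_scalar_num(baseline_mean, "baseline_mean")
  if (baseline_mean <= 0)
    stop("baseline mean intake must be positive", call. = FALSE)
  100 * (intake - baseline_mean) / baseline_mean
}

#' Fit a normal distribution to pooled baseline variability
#'
#' Characterizes session-to-session baseline variation by pooling per-
#' session percent changes from baseline across animals and fitting a
#' normal distribution (sample mean and SD). Goodness of fit is reported as
#' the R-squared between the fitted normal density and the empirical
#' histogram density (Freedman-Diaconis bins, evaluated at bin midpoints).
#' Twice the fitted SD defines the meaningful-change threshold used by
#' [classify_response()].
#'
#' @param pct_changes Pooled per-session percent changes from baseline.
#' @return An object of class `normal_fit`: list with `mean`, `sd`,
#'   `r_squared`, `n`, `breaks`.
#' @export
fit_baseline_distribution <- function(pct_changes) {
  pct_changes <- pct_changes[is.finite(pct_changes)]
  n <- length(pct_changes)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  s <- stats::sd(pct_changes)
  if (s == 0)
    stop("baseline percent changes are constant; SD undefined for the rule",
         call. = FALSE)
  h <- graphics::hist(pct_changes, breaks = "FD", plot = FALSE)
  fitted <- stats::dnorm(h$mids, mean(pct_changes), s)
  ss_res <- sum((h$density - fitted)^2)
  ss_tot <- sum((h$density - mean(h$density))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  structure(list(mean = mean(pct_changes), sd = s, r_squared = r2, n = n,
                 breaks = h$breaks),
            class = "normal_fit")
}

#' @export
print.normal_fit <- function(x, ...) {
  cat(sprintf("<normal_fit> mean %.2f%%, SD %.2f%% (n = %d), R^2 = %s\n",
              x$mean, x$sd, x$n,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared))))
  invisible(x)
}

#' Classify one animal's response to stimulation at one target
#'
#' An animal is a responder to a target when its binge size is reduced by
#' strictly more than the threshold (2 pooled-baseline SDs; 26% by default)
#' in every stimulation session. Sessions with an *increase* beyond the
#' threshold never make a responder; they are flagged separately as
#' paradoxical increases.
#'
#' @param stim_pct Percent changes from baseline for the stimulation
#'   sessions (must have exactly `n_required` values).
#' @param threshold Meaningful-change threshold in percent (default 26, the
#'   2-SD value of the pooled 13%-SD baseline distribution).
#' @param n_required Required number of stimulation sessions (default 3).
#' @return `"responder"` or `"non-responder"`, with attribute
#'   `"paradoxical"` (`TRUE` if any session increased beyond `threshold`).
#' @examples
#' classify_response(c(-30, -28, -35))          # responder
#' classify_response(c(-30, -20, -35))          # non-responder
#' classify_response(c(-26, -27, -28))          # non-responder (strict rule)
#' @export
classify_response <- function(stim_pct, threshold = 26, n_required = 3) {
  if (length(stim_pct) != n_required)
    stop("expected ", n_required, " stimulation sessions, got ",
         length(stim_pct), call. = FALSE)
  stop_if_not_scalar_num(threshold, "threshold", positive = TRUE)
  status <- if (all(stim_pct < -threshold)) "responder" else "non-responder"
  structure(status, paradoxical = any(stim_pct > threshold))
}

#' Assign the optimal stimulation target of one animal
#'
#' Among the targets at which the animal is a responder, picks the one with
#' the largest mean binge-size reduction; animals that respond to no target
#' are `"excluded"`. An exact tie (impossible in continuous data) is broken
#' toward the first target in canonical order with a warning.
#'
#' @param mean_pct Named numeric: mean stimulation percent change per
#'   target.
#' @param status Named character: `"responder"`/`"non-responder"` per
#'   target (same names).
#' @return One of the target names, or `"excluded"`.
#' @export
assign_optimal_target <- function(mean_pct, status) {
  if (is.null(names(mean_pct)) || !identical(sort(names(mean_pct)),
                                             sort(names(status))))
    stop("mean_pct and status must be named over the same targets",
         call. = FALSE)
  resp <- names(status)[status == "responder"]
  if (length(resp) == 0) return("excluded")
  m <- mean_pct[resp]
  best <- resp[m == min(m)]
  if (length(best) > 1) {
    warning("exact tie between targets ", paste(best, collapse = " and "),
            "; broken toward ", best[1], call. = FALSE)
    best <- best[1]
  }
  best
}

#' Label stimulation outcomes for a whole intake table
#'
#' Applies the responder rule target-by-target to an intake table: per
#' animal, the baseline mean is computed from its baseline sessions, each
#' stimulation session is expressed as percent change from that mean, the
#' all-sessions rule classifies responder status per target, and the
#' optimal target is the responder target with the largest mean reduction.
#'
#' @param binge A data frame with columns `animal`, `session_index`,
#'   `session_type`, `target`, `intake_kcal` (as produced by
#'   [simulate_binge_cohort()] or read from CSV).
#' @param threshold Percent threshold; `NULL` (default) recomputes it as
#'   twice the SD fitted by [fit_baseline_distribution()] on the pooled
#'   baseline sessions of this table.
#' @param n_required Required stimulation sessions per target (default 3).
#' @return Data frame of class `outcome_labels`: one row per animal with
#'   per-target status and mean percent change, and `optimal_target`;
#'   attributes `threshold` and `baseline_fit` (if fitted).
#' @export
label_outcomes <- function(binge, threshold = NULL, n_required = 3) {
  need <- c("animal", "session_type", "target", "intake_kcal")
  if (!all(need %in% names(binge)))
    stop("intake table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  fit <- NULL
  if (is.null(threshold)) {
    base <- binge[binge$session_type == "baseline", , drop = FALSE]
    pc <- unlist(lapply(split(base, base$animal), function(d)
      percent_change_from_baseline(d$intake_kcal, mean(d$intake_kcal))))
    fit <- fit_baseline_distribution(pc)
    threshold <- 2 * fit$sd
  }
  targets <- setdiff(unique(binge$target), "none")
  rows <- lapply(split(binge, binge$animal), function(d) {
    bmean <- mean(d$intake_kcal[d$session_type == "baseline"])
    st <- setNames(character(length(targets)), targets)
    mp <- setNames(numeric(length(targets)), targets)
    pd <- setNames(logical(length(targets)), targets)
    for (tg in targets) {
      stim <- d$intake_kcal[d$session_type == "stimulation" & d$target == tg]
      pct <- percent_change_from_baseline(stim, bmean)
      res <- classify_response(pct, threshold, n_required)
      st[tg] <- as.character(res)
      pd[tg] <- attr(res, "paradoxical")
      mp[tg] <- mean(pct)
    }
    out <- data.frame(animal = d$animal[1], stringsAsFactors = FALSE)
    for (tg in targets) {
      out[[paste0(tg, "_status")]] <- st[tg]
      out[[paste0(tg, "_mean_pct")]] <- mp[tg]
      out[[paste0(tg, "_paradoxical")]] <- pd[tg]
    }
    out$optimal_target <- assign_optimal_target(mp, st)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, threshold = threshold, baseline_fit = fit,
            targets = targets,
            class = c("outcome_labels", "data.frame"))
}

#' Aggregate response profiles over a cohort
#'
#' Counts, over animals labelled at both targets, the four mutually
#' exclusive response profiles: responder at the first target only, at the
#' second only, at both, or at neither, plus the single-target total.
#'
#' @param labels An `outcome_labels` data frame from [label_outcomes()] (or
#'   any data frame with `<target>_status` columns for two targets).
#' @param targets The two target names (default from the labels attribute,
#'   else `c("core", "shell")`).
#' @return A list of class `response_profile` with the four counts,
#'   `single_target`, and `n`.
#' @export
summarize_response_profiles <- function(labels,
                                        targets = attr(labels, "targets")) {
  targets <- targets %||% c("core", "shell")
  if (length(targets) != 2L)
    stop("profile aggregation is defined for exactly two targets",
         call. = FALSE)
  cols <- paste0(targets, "_status")
  if (!all(cols %in% names(labels)))
    stop("labels must have columns ", paste(cols, collapse = " and "),
         call. = FALSE)
  bad <- labels$animal[!complete.cases(labels[cols])]
  if (length(bad) > 0)
    stop("missing target label(s) for animal(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  r1 <- labels[[cols[1]]] == "responder"
  r2 <- labels[[cols[2]]] == "responder"
  out <- list(n = nrow(labels))
  out[[paste0(targets[1], "_only")]] <- sum(r1 & !r2)
  out[[paste0(targets[2], "_only")]] <- sum(!r1 & r2)
  out$both <- sum(r1 & r2)
  out$neither <- sum(!r1 & !r2)
  out$single_target <- sum(xor(r1, r2))
  structure(out, targets = targets, class = "response_profile")
}

#' @export
print.response_profile <- function(x, ...) {
  tg <- attr(x, "targets")
  cat(sprintf("<response_profile> n = %d: %s-only %d, %s-only %d, both %d, neither %d (single-target %d/%d)\n",
              x$n, tg[1], x[[paste0(tg[1], "_only")]],
              tg[2], x[[paste0(tg[2], "_only")]],
              x$both, x$neither, x$single_target, x$n))
  invisible(x)
}
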