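# Class-resolved differential splicing on Psi values. Events are
# compared between reactivated (positive) and silent (negative) sample
# groups; a call requires both a significant one-sided Mann-Whitney
# p-value and a Psi difference beyond the border, which makes the
# composite test conservative on null data.

#' Differential splicing between two sample groups
#'
#' Per event, `delta_psi` is the difference of group means of
#' non-missing Psi (positive minus negative); the p-value is a
#' one-sided Mann-Whitney test in the direction of `delta_psi`. The
#' call is `up` iff `p < alpha` and `delta_psi > delta`, `down` iff
#' `p < alpha` and `delta_psi < -delta`, else `none`. Events with fewer
#' than `min_per_group` non-missing values in either group are skipped
#' and reported as untested (`tested = FALSE`).
#'
#' @param psi a `PsiTable`.
#' @param group_pos,group_neg disjoint sample-id sets.
#' @param alpha significance level (default 0.05).
#' @param delta Psi-difference border (default 0.1).
#' @param min_per_group minimum non-missing Psi per group (default 5).
#' @param location `"mean"` (default) or `"median"` for the per-group
#'   Psi summary behind `delta_psi`.
#' @return `data.frame` with `event_id`, `event_class`, `n_pos`,
#'   `n_neg`, `delta_psi`, `p_value`, `call`, `tested`.
#' @export
differential_splicing <- function(psi, group_pos, group_neg,
                                  alpha = 0.05, delta = 0.1,
                                  min_per_group = 5,
                                  location = c("mean", "median")) {
  stopifnot(inherits(psi, "PsiTable"))
  location <- match.arg(location)
  if (length(intersect(group_pos, group_neg))) stop("groups overlap")
  if (length(group_pos) == 0L || length(group_neg) == 0L)
    stop("both groups must be non-empty")
  miss <- setdiff(c(group_pos, group_neg), colnames(psi$psi))
  if (length(miss)) stop("sample(s) not in Psi table: ", miss[1L])
  loc_fun <- if (location == "mean") mean else median
  nev <- length(psi$event_id)
  n_pos <- n_neg <- integer(nev)
  delta_psi <- p_value <- rep(NA_real_, nev)
  call <- rep("none", nev)
  tested <- logical(nev)
  mp <- psi$psi[, group_pos, drop = FALSE]
  mn <- psi$psi[, group_neg, drop = FALSE]
  for (i in seq_len(nev)) {
    xp <- mp[i, ]; xp <- xp[!is.na(xp)]
    xn <- mn[i, ]; xn <- xn[!is.na(xn)]
    n_pos[i] <- length(xp); n_neg[i] <- length(xn)
    if (length(xp) < min_per_group || length(xn) < min_per_group) next
    tested[i] <- TRUE
    dpsi <- loc_fun(xp) - loc_fun(xn)
    alt <- if (dpsi >= 0) "x_greater" else "x_less"
    p <- mann_whitney_u(xp, xn, alternative = alt)$p
    delta_psi[i] <- dpsi; p_value[i] <- p
    if (p < alpha && dpsi > delta) call[i] <- "up"
    else if (p < alpha && dpsi < -delta) call[i] <- "down"
  }
  data.frame(event_id = psi$event_id, event_class = psi$event_class,
             n_pos = n_pos, n_neg = n_neg, delta_psi = delta_psi,
             p_value = p_value, call = call, tested = tested,
             stringsAsFactors = FALSE)
}

#' Per-class tallies of splicing calls
#'
#' Percentages are relative to tested events of the class. Classes with
#' no tested event are reported with `n_tested = 0` and `NA`
#' percentages (undefined, not zero).
#'
#' @param calls output of [differential_splicing()].
#' @param classes event classes to report (default: all classes present
#'   in `calls`).
#' @return `data.frame` with `event_class`, `n_events`, `n_tested`,
#'   `n_up`, `n_down`, `pct_up`, `pct_down`.
#' @export
class_tallies <- function(calls, classes = unique(calls$event_class)) {
  out <- do.call(rbind, lapply(classes, function(cl) {
    d <- calls[calls$event_class == cl, ]
    nt <- sum(d$tested)
    data.frame(event_class = cl, n_events = nrow(d), n_tested = nt,
               n_up = sum(d$call == "up"), n_down = sum(d$call == "down"),
               pct_up = if (nt > 0) 100 * sum(d$call == "up") / nt else NA_real_,
               pct_down = if (nt > 0) 100 * sum(d$call == "down") / nt else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
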