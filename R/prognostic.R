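#' Fit a linear ranking survival SVM
#'
#' Ranking formulation over comparable pairs: minimize
#' `0.5 * ||w||^2 + gamma * sum over comparable (i, j) of
#' max(0, 1 - w . (x_i - x_j))`, where pair `(i, j)` is comparable iff
#' sample `j`'s observed time is shorter than sample `i`'s and `j`
#' experienced the event. `w . x` is a survival-time score (higher = later
#' predicted event), so features enriched in early-failing samples receive
#' negative coefficients. Solved by gradient descent with Armijo
#' backtracking; recorded objective values are non-increasing by
#' construction.
#'
#' @param x Feature matrix (samples x features), typically binary carriers.
#' @param time Observed times.
#' @param event Event indicators (1 = recurrence observed).
#' @param gamma Hinge penalty weight (> 0, default 1).
#' @param max_iter Maximum accepted descent steps.
#' @param tol Relative objective-decrease convergence tolerance.
#' @return List of class `survival_svm`: `coefficients` (named),
#'   `objective` (per accepted iteration), `n_pairs`, `converged`.
#' @export
fit_survival_svm <- function(x, time, event, gamma = 1, max_iter = 200,
                             tol = 1e-6) {
  x <- as.matrix(x)
  if (gamma <= 0) stop("gamma must be > 0")
  if (sum(event) == 0) stop("no events; ranking objective undefined")
  if (any(time < 0)) stop("negative times")
  n <- nrow(x)
  # comparable pairs: j failed before i was observed
  pr <- which(outer(time, time, ">") &
                matrix(event == 1, n, n, byrow = TRUE), arr.ind = TRUE)
  if (nrow(pr) < 2) stop("fewer than 2 comparable pairs")
  D <- x[pr[, 1], , drop = FALSE] - x[pr[, 2], , drop = FALSE]

  obj <- function(w) {
    margins <- 1 - drop(D %*% w)
    0.5 * sum(w^2) + gamma * sum(pmax(margins, 0))
  }
  grad <- function(w) {
    active <- drop(D %*% w) < 1
    w - gamma * drop(crossprod(D, active))
  }

  w <- rep(0, ncol(x))
  f <- obj(w)
  path <- f
  step0 <- 1 / (1 + gamma * sum(D^2) / nrow(D))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- grad(w)
    step <- step0
    accepted <- FALSE
    for (bt in 1:40) {
      w_new <- w - step * g
      f_new <- obj(w_new)
      if (f_new <= f - 1e-4 * step * sum(g^2)) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    if ((f - f_new) <= tol * max(1, abs(f))) {
      w <- w_new; path <- c(path, f_new); converged <- TRUE; break
    }
    w <- w_new; f <- f_new; path <- c(path, f)
  }
  names(w) <- colnames(x) %||% sprintf("V%d", seq_len(ncol(x)))
  structure(list(coefficients = w, objective = path, n_pairs = nrow(D),
                 gamma = gamma, converged = converged),
            class = "survival_svm")
}

#' Rank deletions by survival-SVM coefficient magnitude
#'
#' Sorts by `|coefficient|` descending, ties broken by original column
#' order, and returns the first `k`.
#'
#' @param coefficients Named coefficient vector (or a `survival_svm` fit).
#' @param k How many to return.
#' @return Character vector of the top-k feature ids, in rank order.
#' @export
rank_prognostic_dsvs <- function(coefficients, k) {
  if (inherits(coefficients, "survival_svm"))
    coefficients <- coefficients$coefficients
  if (k > length(coefficients)) stop("k exceeds the number of features")
  ord <- order(-abs(coefficients), seq_along(coefficients))
  names(coefficients)[ord][seq_len(k)]
}

#' Univariate Cox proportional hazards fit for one binary feature
#'
#' Maximizes the Cox partial likelihood (Efron tie handling, Newton-type
#' optimization via the survival package) and reports the Wald test.
#' Monotone-likelihood/separation problems are flagged rather than silently
#' returned.
#'
#' @param x Binary (or numeric) covariate vector.
#' @param time Observed times.
#' @param event Event indicators.
#' @return List with `loghr`, `se`, `p`, `flagged`.
#' @export
cox_univariate <- function(x, time, event) {
  if (length(unique(x)) < 2) stop("constant covariate; Cox fit undefined")
  if (any(time < 0)) stop("negative times")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"),
    warning = function(w) invokeRestart("muffleWarning"))
  s <- summary(fit)
  loghr <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(fit$var)))
  flagged <- !is.finite(loghr) || abs(loghr) > 15 || se > 100
  list(loghr = loghr, se = se, p = unname(s$coefficients[, "Pr(>|z|)"]),
       flagged = flagged)
}

#' Partition deletions by the sign of their Cox log hazard ratio
#'
#' Each deletion gets a univariate Cox fit against recurrence-free
#' survival; positive log HR makes it recurrence-associated, negative (or
#' exactly zero, conservatively) non-recurrence-associated. Deletions whose
#' Cox fit fails or is flagged are dropped with a warning. The per-deletion
#' p-values support a volcano display (log2 HR vs -log10 p).
#'
#' @param carriers A `carrier_matrix` or binary matrix.
#' @param time,event Survival outcome per sample (rows of `carriers`).
#' @param dsv_ids Deletions to partition (default: all columns), e.g. the
#'   output of [rank_prognostic_dsvs()].
#' @param svm_coefficients Optional named survival-SVM coefficients to
#'   carry along.
#' @return data.frame of class `prognostic_partition`: `dsv_id`, `rank`,
#'   `svm_coef`, `loghr`, `se`, `p`, `group`.
#' @export
partition_by_hazard <- function(carriers, time, event, dsv_ids = NULL,
                                svm_coefficients = NULL) {
  X <- if (inherits(carriers, "carrier_matrix")) carriers$carriers else carriers
  if (is.null(dsv_ids)) dsv_ids <- colnames(X)
  if (length(dsv_ids) == 0) stop("empty deletion set")
  rows <- list()
  dropped <- character(0)
  for (i in seq_along(dsv_ids)) {
    id <- dsv_ids[i]
    res <- tryCatch(cox_univariate(X[, id], time, event), error = function(e) NULL)
    if (is.null(res) || res$flagged) { dropped <- c(dropped, id); next }
    rows[[id]] <- data.frame(
      dsv_id = id, rank = i,
      svm_coef = if (is.null(svm_coefficients)) NA_real_ else unname(svm_coefficients[id]),
      loghr = res$loghr, se = res$se, p = res$p,
      group = if (res$loghr > 0) "recurrence-associated" else "non-recurrence-associated",
      stringsAsFactors = FALSE)
  }
  if (length(dropped) > 0)
    warning(length(dropped), " deletion(s) dropped (Cox fit failed or flagged): ",
            paste(utils::head(dropped, 5), collapse = ", "))
  if (length(rows) == 0) stop("no deletion survived the Cox fits")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("prognostic_partition", "data.frame")
  out
}

#' Stratify patients into G1/G2 by carried prognostic deletions
#'
#' Per patient, `R` counts carried recurrence-associated deletions and `P`
#' carried non-recurrence-associated deletions. G1 (poor prognosis) iff
#' `R > P`; ties (including carrying none) go to G2.
#'
#' @param carriers A `carrier_matrix` or binary matrix.
#' @param partition A [partition_by_hazard()] result.
#' @return data.frame with `sample_id`, `R`, `P`, `group`.
#' @export
stratify_patients <- function(carriers, partition) {
  X <- if (inherits(carriers, "carrier_matrix")) carriers$carriers else carriers
  if (nrow(partition) == 0) stop("empty partition")
  rec <- partition$dsv_id[partition$group == "recurrence-associated"]
  non <- partition$dsv_id[partition$group == "non-recurrence-associated"]
  R <- if (length(rec)) rowSums(X[, rec, drop = FALSE]) else rep(0L, nrow(X))
  P <- if (length(non)) rowSums(X[, non, drop = FALSE]) else rep(0L, nrow(X))
  data.frame(sample_id = rownames(X) %||% seq_len(nrow(X)),
             R = as.integer(R), P = as.integer(P),
             group = ifelse(R > P, "G1", "G2"),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator via [survival::survfit()], returned as a tidy
#' step-function table with the `S(0) = 1` anchor row per group.
#'
#' @param time,event Survival outcome.
#' @param groups Group label per sample (single group if `NULL`).
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
kaplan_meier <- function(time, event, groups = NULL) {
  if (any(time < 0)) stop("negative times")
  if (is.null(groups)) groups <- rep("all", length(time))
  df <- data.frame(time = time, event = event, group = as.character(groups))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- if (is.null(fit$strata)) stats::setNames(length(fit$time), unique(df$group))
            else fit$strata
  grp <- rep(sub("^group=", "", names(strata)), strata)
  out <- data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv, stringsAsFactors = FALSE)
  anchor <- do.call(rbind, lapply(split(out, out$group), function(d)
    data.frame(group = d$group[1], time = 0, n_risk = max(d$n_risk),
               n_event = 0, n_censor = 0, surv = 1, stringsAsFactors = FALSE)))
  out <- rbind(anchor, out)
  out <- out[order(out$group, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-group log-rank test
#'
#' `(O - E)^2 / V` with the hypergeometric variance summed over distinct
#' event times; p from chi-square on 1 df. With no events the statistic is
#' 0 and p = 1.
#'
#' @param time,event Survival outcome.
#' @param groups Group label per sample; exactly two distinct groups.
#' @return List with `statistic` and `p`.
#' @export
logrank_test <- function(time, event, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) != 2) stop("log-rank test needs exactly 2 groups")
  if (sum(event) == 0) return(list(statistic = 0, p = 1))
  df <- data.frame(time = time, event = event, group = groups)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(statistic = unname(sd_$chisq),
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}
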