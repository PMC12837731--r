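# Epoch-association statistics: cluster x epoch contingency tables, Pearson
# chi-square, multinomial logistic regression with Wald CIs, Tukey-Kramer
# HSD, and (age-adjusted) linear regression of features on epoch.

#' Cross-tabulate cluster assignments against epochs
#'
#' @param clusters cluster labels (coercible to factor).
#' @param epochs epoch labels; `"unassigned"` is not allowed here.
#' @return an `hfo_contingency`: list with `counts` (cluster x epoch integer
#'   matrix) and `row_pct` (row percentages, each row summing to 100).
#' @export
build_contingency <- function(clusters, epochs) {
  if (length(clusters) != length(epochs) || length(clusters) == 0)
    stop("cluster and epoch labels must have equal positive length", call. = FALSE)
  if (any(epochs == "unassigned"))
    stop("events with unassigned epochs must be excluded first", call. = FALSE)
  bad <- !epochs %in% epoch_levels()
  if (any(bad))
    stop("unknown epoch label(s): ", paste(unique(epochs[bad]), collapse = ", "),
         call. = FALSE)
  cl <- factor(paste0("cluster", clusters))
  ep <- factor(epochs, levels = intersect(epoch_levels(), unique(epochs)))
  counts <- unclass(table(cl, ep))
  structure(list(counts = counts,
                 row_pct = 100 * counts / rowSums(counts)),
            class = "hfo_contingency")
}

#' @export
print.hfo_contingency <- function(x, ...) {
  cat("<hfo_contingency> counts (row %):\n")
  m <- matrix(sprintf("%d (%.1f)", x$counts, x$row_pct),
              nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(m, quote = FALSE)
  invisible(x)
}

#' Pearson chi-square test of a cluster x epoch table
#'
#' Two-tailed Pearson test without continuity correction: statistic
#' sum((O - E)^2 / E) with expected counts from the margins, df =
#' (r - 1)(c - 1), upper-tail p-value.
#'
#' @param tab an `hfo_contingency` or a count matrix.
#' @return list: `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(tab) {
  counts <- if (inherits(tab, "hfo_contingency")) tab$counts else as.matrix(tab)
  if (sum(counts) == 0) stop("empty table", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: zero row or column margin", call. = FALSE)
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Multinomial logistic regression of epoch on cluster
#'
#' Maximum-likelihood multinomial logit with a dummy-coded cluster
#' predictor. For this saturated single-factor design the fitted cell
#' probabilities equal the empirical proportions and every odds ratio
#' equals the corresponding cross-product ratio of counts. Confidence
#' intervals are Wald on the log-odds scale.
#'
#' @param epochs outcome labels (3 epoch levels).
#' @param clusters predictor labels.
#' @param outcome_ref reference epoch, default the interictal epoch of
#'   seizure-free patients.
#' @param predictor_ref reference cluster, default `1`.
#' @return an `hfo_multinomial_fit`: list with `coefficients` (data frame:
#'   outcome, term, beta, se, or, ci_lo, ci_hi, p, infinite flag),
#'   `fitted_probs` (per-cluster fitted epoch probabilities),
#'   `log_likelihood`, `converged`.
#' @export
multinomial_logit <- function(epochs, clusters,
                              outcome_ref = "interictal_seizure_free",
                              predictor_ref = "1") {
  ep <- factor(epochs)
  ep <- stats::relevel(ep, ref = outcome_ref)
  cl <- factor(paste0("cluster", clusters))
  cl <- stats::relevel(cl, ref = paste0("cluster", predictor_ref))
  d <- data.frame(ep = ep, cl = cl)
  fit <- nnet::multinom(ep ~ cl, data = d, trace = FALSE,
                        maxit = 1000, reltol = 1e-14)
  co <- coef(fit)
  se <- summary(fit)$standard.errors
  if (!is.matrix(co)) {          # two outcome levels: multinom returns vectors
    co <- matrix(co, nrow = 1, dimnames = list(levels(ep)[2], names(co)))
    se <- matrix(se, nrow = 1, dimnames = dimnames(co))
  }
  zcrit <- qnorm(0.975)
  rows <- list()
  for (i in seq_len(nrow(co))) for (j in seq_len(ncol(co))) {
    if (colnames(co)[j] == "(Intercept)") next
    b <- co[i, j]; s <- se[i, j]
    z <- b / s
    rows[[length(rows) + 1]] <- data.frame(
      outcome = rownames(co)[i],
      term = colnames(co)[j],
      beta = b, se = s, or = exp(b),
      ci_lo = exp(b - zcrit * s), ci_hi = exp(b + zcrit * s),
      p = 2 * stats::pnorm(-abs(z)),
      infinite = abs(b) > 15,
      stringsAsFactors = FALSE)
  }
  probs <- fitted(fit)
  probs <- probs[!duplicated(d$cl), , drop = FALSE]
  rownames(probs) <- as.character(d$cl[!duplicated(d$cl)])
  structure(list(coefficients = do.call(rbind, rows),
                 fitted_probs = probs[order(rownames(probs)), , drop = FALSE],
                 log_likelihood = -fit$value,
                 converged = fit$convergence == 0,
                 outcome_ref = outcome_ref, predictor_ref = predictor_ref),
            class = "hfo_multinomial_fit")
}

#' Tukey-Kramer honestly-significant-difference test
#'
#' All-pairs comparison of group means controlling the familywise error via
#' the studentized range, valid for unequal group sizes. For pair (i, j):
#' `q = |mean_i - mean_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))`, with adjusted
#' p-values from the studentized-range distribution on (N - g) degrees of
#' freedom.
#'
#' @param values numeric measurements.
#' @param groups group labels (>= 2 groups of >= 2 observations).
#' @return data frame: `group_a`, `group_b`, `diff` (mean_b - mean_a),
#'   `se`, `q`, `p_adj`.
#' @export
tukey_kramer_hsd <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  N <- length(values)
  k <- nlevels(g)
  mse <- sum(tapply(values, g, function(v) sum((v - mean(v))^2))) / (N - k)
  pairs <- utils::combn(levels(g), 2)
  out <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    se <- sqrt(mse / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
    q <- abs(means[[b]] - means[[a]]) / se
    data.frame(group_a = a, group_b = b,
               diff = means[[b]] - means[[a]], se = se, q = q,
               p_adj = ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Linear regression of a feature on epoch, optionally age-adjusted
#'
#' Least-squares fit with dummy-coded epoch (stated reference level) and an
#' optional age covariate; t-based 95% CIs and standardized coefficients
#' (`beta * SD(x) / SD(y)`).
#'
#' @param response feature values.
#' @param epochs epoch labels.
#' @param age optional age covariate (years).
#' @param ref reference epoch level.
#' @return an `hfo_ols_fit`: data frame of terms with `beta`, `ci_lo`,
#'   `ci_hi`, `std_beta`, `p`; attribute `adjusted` records whether age was
#'   included.
#' @export
ols_regression <- function(response, epochs, age = NULL,
                           ref = "interictal_seizure_free") {
  ep <- stats::relevel(factor(epochs), ref = ref)
  d <- data.frame(y = response, ep = ep)
  form <- y ~ ep
  if (!is.null(age)) { d$age <- age; form <- y ~ ep + age }
  X <- stats::model.matrix(form, d)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  fit <- lm(form, data = d)
  ci <- confint(fit)
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)[-1]
  out <- data.frame(
    term = sub("^ep", "", terms),
    beta = sm[-1, "Estimate"],
    ci_lo = ci[-1, 1], ci_hi = ci[-1, 2],
    std_beta = vapply(terms, function(tm)
      sm[tm, "Estimate"] * sd(X[, tm]) / sd(d$y), 0),
    p = sm[-1, "Pr(>|t|)"],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, adjusted = !is.null(age), class = c("hfo_ols_fit", "data.frame"))
}

format_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))

#' Write report tables for the phenotyping analysis
#'
#' Emits the cluster x epoch count table with row percentages and the
#' multinomial odds ratios (one CSV), the per-feature regression table with
#' crude and age-adjusted coefficients (one CSV), and a JSON summary of all
#' fitted statistics. Regeneration is byte-identical for identical inputs.
#'
#' @param contingency an `hfo_contingency`.
#' @param chi result of [chi_square_test()].
#' @param mfit an `hfo_multinomial_fit` (or `NULL`).
#' @param ols_fits named list of `hfo_ols_fit` objects (or `NULL`), e.g.
#'   `list(avg_frequency_crude = ..., avg_frequency_adjusted = ...)`.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
make_reports <- function(contingency, chi, mfit = NULL, ols_fits = NULL,
                         dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- contingency$counts
  if (any(rowSums(counts) == 0))
    warning("empty cluster row in the contingency table")
  pct <- contingency$row_pct
  pct[is.nan(pct)] <- 0
  t2 <- data.frame(cluster = rownames(counts), stringsAsFactors = FALSE)
  for (ep in colnames(counts)) {
    t2[[paste0(ep, "_n")]] <- counts[, ep]
    t2[[paste0(ep, "_pct")]] <- round(pct[, ep], 1)
  }
  if (!is.null(mfit)) {
    cf <- mfit$coefficients
    for (out in unique(cf$outcome)) {
      t2[[paste0(out, "_or")]] <- NA_real_
      t2[[paste0(out, "_ci")]] <- NA_character_
      t2[[paste0(out, "_p")]] <- NA_character_
    }
    for (i in seq_len(nrow(cf))) {
      cl <- sub("^cl", "", cf$term[i])
      row <- match(cl, t2$cluster)
      pre <- paste0(cf$outcome[i], "_")
      t2[[paste0(pre, "or")]][row] <- round(cf$or[i], 2)
      t2[[paste0(pre, "ci")]][row] <- sprintf("%.2f-%.2f", cf$ci_lo[i], cf$ci_hi[i])
      t2[[paste0(pre, "p")]][row] <- format_p(cf$p[i])
    }
  }
  f_t2 <- file.path(dir, "table2.csv")
  write.csv(t2, f_t2, row.names = FALSE)

  files <- c(table2 = f_t2)
  if (!is.null(ols_fits)) {
    t3 <- do.call(rbind, lapply(names(ols_fits), function(nm) {
      f <- ols_fits[[nm]]
      data.frame(model = nm, term = f$term, beta = round(f$beta, 3),
                 ci = sprintf("%.3f to %.3f", f$ci_lo, f$ci_hi),
                 std_beta = round(f$std_beta, 3), p = format_p(f$p),
                 stringsAsFactors = FALSE)
    }))
    f_t3 <- file.path(dir, "table3.csv")
    write.csv(t3, f_t3, row.names = FALSE)
    files <- c(files, table3 = f_t3)
  }
  js <- list(chi_square = chi,
             counts = counts, row_pct = round(pct, 1))
  if (!is.null(mfit)) js$multinomial <- mfit$coefficients
  if (!is.null(ols_fits)) js$ols <- ols_fits
  f_js <- file.path(dir, "stats.json")
  jsonlite::write_json(js, f_js, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  files <- c(files, stats = f_js)
  invisible(files)
}
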