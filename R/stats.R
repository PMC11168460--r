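## Inference layer over per-bead and per-condensate tables: unpaired t
## tests, two-way ANOVA and the linear mixed model with replicate and well
## as random factors.

#' Unpaired two-tailed Student's t test
#'
#' Pooled-variance Student statistic with a two-sided p-value on
#' n_a + n_b - 2 degrees of freedom. Degenerate inputs (zero pooled
#' variance) are resolved explicitly: equal means give t = 0, p = 1;
#' unequal means give an unbounded statistic with a vanishing p-value and a
#' degeneracy flag.
#'
#' @param a,b numeric response vectors, each of length >= 2.
#' @return list of class \code{TestResult}: \code{statistic}, \code{df},
#'   \code{p_value}, \code{meanA}, \code{meanB}, \code{nA}, \code{nB},
#'   \code{degenerate}.
#' @examples
#' tTestUnpaired(c(1, 2, 3), c(2, 3, 4))
#' @export
tTestUnpaired <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  df <- length(a) + length(b) - 2L
  pooled <- ((length(a) - 1) * stats::var(a) +
             (length(b) - 1) * stats::var(b)) / df
  if (pooled == 0) {
    if (mean(a) == mean(b))
      return(structure(list(statistic = 0, df = df, p_value = 1,
                            meanA = mean(a), meanB = mean(b),
                            nA = length(a), nB = length(b),
                            degenerate = FALSE), class = "TestResult"))
    return(structure(list(statistic = sign(mean(a) - mean(b)) * Inf, df = df,
                          p_value = .Machine$double.xmin,
                          meanA = mean(a), meanB = mean(b),
                          nA = length(a), nB = length(b),
                          degenerate = TRUE), class = "TestResult"))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = max(ht$p.value, .Machine$double.xmin),
                 meanA = mean(a), meanB = mean(b),
                 nA = length(a), nB = length(b), degenerate = FALSE),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("Unpaired two-tailed t test: t = %.4g, df = %g, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$degenerate) " [degenerate: zero pooled variance]" else ""))
  cat(sprintf("  group means %.4g (n = %d) vs %.4g (n = %d)\n",
              x$meanA, x$nA, x$meanB, x$nB))
  invisible(x)
}

#' Linear mixed model for bead measurements
#'
#' Fits \code{response ~ condition + (1 | replicate) + (1 | replicate:well)}
#' by REML: a fixed condition effect with random intercepts for experiment
#' replicate and for well nested in replicate. Well labels may repeat across
#' replicates (as on real plates) and are disambiguated internally as
#' \code{replicate:well}. Fixed-effect contrasts are tested with Wald t
#' statistics; denominator degrees of freedom use the Satterthwaite
#' approximation by default (\code{pMethod = "wald"} uses the normal
#' reference instead). Singular fits (a variance component estimated on the
#' boundary) are flagged, never hidden.
#'
#' Apply [qcFilter()] before modeling; beads failing QC should not enter the
#' fit.
#'
#' @param table data.frame with the response and grouping columns.
#' @param response response column name (default \code{"mean_score"}).
#' @param condition fixed-factor column name.
#' @param replicate,well random-factor column names.
#' @param pMethod \code{"satterthwaite"} (default) or \code{"wald"}.
#' @return a [MixedModelResult-class].
#' @export
fitBeadMixedModel <- function(table, response = "mean_score",
                              condition = "condition",
                              replicate = "replicate_id", well = "well_id",
                              pMethod = c("satterthwaite", "wald")) {
  pMethod <- match.arg(pMethod)
  need <- c(response, condition, replicate, well)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  table <- as.data.frame(table)
  ## reference level = first condition encountered in the table
  table$.cond <- factor(table[[condition]],
                        levels = unique(table[[condition]]))
  if (nlevels(table$.cond) < 2L) stop("need >= 2 conditions")
  tooFew <- names(which(table(table$.cond) < 2L))
  if (length(tooFew))
    stop("condition with a single bead: ", paste(tooFew, collapse = ", "))
  table$.rep <- factor(table[[replicate]])
  table$.well <- factor(paste(table[[replicate]], table[[well]], sep = ":"))
  ## a physical well holds exactly one condition; mixed labels indicate a
  ## mislabeled (non-nested) table
  mixed <- tapply(table$.cond, table$.well, function(x) length(unique(x)))
  if (any(mixed > 1L))
    stop("non-nested well labels: well(s) ",
         paste(names(which(mixed > 1L)), collapse = ", "),
         " carry multiple conditions")
  table$.y <- table[[response]]
  fit <- suppressMessages(lmerTest::lmer(
    .y ~ .cond + (1 | .rep) + (1 | .well), data = table, REML = TRUE))
  singular <- lme4::isSingular(fit)
  co <- stats::coef(summary(fit))
  idx <- grep("^\\.cond", rownames(co))
  terms <- sub("^\\.cond", "", rownames(co)[idx])
  if (pMethod == "satterthwaite") {
    fe <- data.frame(term = terms, estimate = co[idx, "Estimate"],
                     se = co[idx, "Std. Error"], df = co[idx, "df"],
                     statistic = co[idx, "t value"],
                     p_value = pmax(co[idx, "Pr(>|t|)"],
                                    .Machine$double.xmin))
  } else {
    z <- co[idx, "Estimate"] / co[idx, "Std. Error"]
    fe <- data.frame(term = terms, estimate = co[idx, "Estimate"],
                     se = co[idx, "Std. Error"], df = NA_real_,
                     statistic = z,
                     p_value = pmax(2 * stats::pnorm(-abs(z)),
                                    .Machine$double.xmin))
  }
  rownames(fe) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcomp <- data.frame(
    group = c("well:replicate", "replicate", "residual"),
    sd = c(vc$sdcor[vc$grp == ".well"], vc$sdcor[vc$grp == ".rep"],
           vc$sdcor[vc$grp == "Residual"]),
    variance = c(vc$vcov[vc$grp == ".well"], vc$vcov[vc$grp == ".rep"],
                 vc$vcov[vc$grp == "Residual"]))
  gs <- do.call(rbind, lapply(levels(table$.cond), function(cl) {
    sub <- table[table$.cond == cl, ]
    data.frame(condition = cl, n_beads = nrow(sub),
               n_wells = length(unique(sub$.well)),
               n_replicates = length(unique(sub$.rep)))
  }))
  new("MixedModelResult", fixedEffects = fe, varComp = vcomp,
      groupSizes = gs, singular = singular, pMethod = pMethod, model = fit)
}

#' Two-way ANOVA with Type II sums of squares
#'
#' Main effects and interaction for a two-factor layout (balanced or
#' unbalanced), using Type II sums of squares. Degenerate layouts are
#' resolved explicitly: with zero residual variance, a factor with zero
#' effect sum of squares reports F = 0, p = 1, and a factor with signal
#' reports an unbounded F with a vanishing p-value.
#'
#' @param table data.frame.
#' @param response,factorA,factorB column names.
#' @param interaction include the A:B interaction (default TRUE); requires
#'   n >= 2 in every non-empty cell and no empty cells.
#' @return data.frame with columns \code{term}, \code{sum_sq}, \code{df},
#'   \code{F}, \code{p_value}.
#' @export
twoWayAnova <- function(table, response, factorA, factorB,
                        interaction = TRUE) {
  table <- as.data.frame(table)
  table$.A <- factor(table[[factorA]])
  table$.B <- factor(table[[factorB]])
  table$.y <- table[[response]]
  cells <- table(table$.A, table$.B)
  if (interaction && any(cells == 0L))
    stop("empty factor cells; cannot estimate the interaction")
  if (interaction && any(cells < 2L))
    stop("interaction requires n >= 2 per cell")
  form <- if (interaction) .y ~ .A * .B else .y ~ .A + .B
  fit <- stats::lm(form, data = table)
  an <- tryCatch(car::Anova(fit, type = 2),
                 error = function(e) typeIIbyRss(table, interaction))
  out <- data.frame(term = sub("^\\.A:\\.B$", paste0(factorA, ":", factorB),
                               sub("^\\.B$", factorB,
                                   sub("^\\.A$", factorA, rownames(an)))),
                    sum_sq = an[["Sum Sq"]], df = an[["Df"]],
                    F = an[["F value"]], p_value = an[["Pr(>F)"]])
  rownames(out) <- NULL
  resid <- out$term == "Residuals"
  residMS <- out$sum_sq[resid] / out$df[resid]
  tol <- max(abs(table$.y), 1) * 1e-12
  if (residMS < tol) {
    eff <- !resid
    zero <- out$sum_sq < tol
    out$F[eff & zero] <- 0
    out$p_value[eff & zero] <- 1
    out$F[eff & !zero] <- Inf
    out$p_value[eff & !zero] <- .Machine$double.xmin
  }
  out$p_value[!resid] <- pmax(out$p_value[!resid], .Machine$double.xmin)
  out
}

## Type II sums of squares from nested-model RSS differences; used when the
## saturated fit is degenerate (zero residual variance) and the standard
## route refuses to divide
typeIIbyRss <- function(table, interaction) {
  rss <- function(f) sum(stats::resid(stats::lm(f, data = table))^2)
  dfTerm <- function(f1, f0)
    length(stats::lm(f1, data = table)$coefficients) -
      length(stats::lm(f0, data = table)$coefficients)
  full <- if (interaction) .y ~ .A * .B else .y ~ .A + .B
  rows <- list(
    ".A" = c(rss(.y ~ .B) - rss(.y ~ .A + .B), dfTerm(.y ~ .A + .B, .y ~ .B)),
    ".B" = c(rss(.y ~ .A) - rss(.y ~ .A + .B), dfTerm(.y ~ .A + .B, .y ~ .A)))
  if (interaction)
    rows[[".A:.B"]] <- c(rss(.y ~ .A + .B) - rss(.y ~ .A * .B),
                         dfTerm(.y ~ .A * .B, .y ~ .A + .B))
  rows[["Residuals"]] <- c(rss(full),
                           nrow(table) -
                             length(stats::lm(full, data = table)$coefficients))
  an <- data.frame(`Sum Sq` = vapply(rows, `[`, numeric(1), 1),
                   Df = vapply(rows, `[`, numeric(1), 2),
                   check.names = FALSE)
  ms <- an$`Sum Sq` / an$Df
  resMS <- ms[rownames(an) == "Residuals"]
  an$`F value` <- c(ms[-nrow(an)] / resMS, NA)
  an$`Pr(>F)` <- c(stats::pf(an$`F value`[-nrow(an)], an$Df[-nrow(an)],
                             an$Df[nrow(an)], lower.tail = FALSE), NA)
  an
}
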