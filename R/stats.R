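## Statistics stage: mixed repeated-measures ANOVA, Bonferroni level,
## equal-variance two-sample t-tests, hypercapnia window magnitude, and a
## magnitude-level cohort generator for calibration studies.

#' Assemble a long-format magnitude table
#'
#' One row per (subject, within-factor level, species): the input format
#' of \code{\link{rmAnovaTwoWay}}.
#'
#' @param subject,group,level,species,magnitude equal-length vectors.
#' @return data.frame with those columns.
#' @export
longTable <- function(subject, group, level, species, magnitude) {
  data.frame(subject = as.character(subject), group = as.character(group),
             level = as.character(level), species = as.character(species),
             magnitude = as.numeric(magnitude), stringsAsFactors = FALSE)
}

#' Two-way mixed repeated-measures ANOVA
#'
#' Mixed design with a between-subject factor (group) and a
#' within-subject factor (session or experiment), fitted by the classical
#' error-strata decomposition: the group effect is tested against the
#' between-subject (subject-within-group) stratum, the within-subject
#' effect and the interaction against the subject-by-level residual
#' stratum. No sphericity correction is applied by default.
#'
#' @param table long-format data.frame from \code{\link{longTable}}.
#' @param species which species' rows to analyse ("Hbt", "Hbo", "Hbr" or
#'   whatever labels the table uses).
#' @return An \linkS4class{AnovaResult}.
#' @export
rmAnovaTwoWay <- function(table, species) {
  d <- table[table$species == species, , drop = FALSE]
  if (!nrow(d)) stop("no rows for species ", species)
  d$subject <- factor(d$subject)
  d$group <- factor(d$group)
  d$level <- factor(d$level)
  if (nlevels(d$group) != 2)
    stop("expected exactly 2 groups, got ", nlevels(d$group))
  ## balance check: every subject must have every level exactly once
  tab <- table(d$subject, d$level)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stop("unbalanced table; missing or duplicated cells: ",
         paste(sprintf("%s x %s", rownames(tab)[bad[, 1]],
                       colnames(tab)[bad[, 2]]), collapse = ", "))
  }
  subjGroup <- unique(d[, c("subject", "group")])
  if (any(table(subjGroup$group) < 2))
    stop("need at least 2 subjects per group")

  fit <- aov(magnitude ~ group * level + Error(subject / level), data = d)
  sm <- summary(fit)
  betw <- sm[["Error: subject"]][[1]]
  with <- sm[["Error: subject:level"]][[1]]
  rn <- function(x) trimws(rownames(x))
  pick <- function(strat, name) {
    i <- match(name, rn(strat))
    c(ss = strat[i, "Sum Sq"], df = strat[i, "Df"],
      F = strat[i, "F value"], p = strat[i, "Pr(>F)"])
  }
  g <- pick(betw, "group")
  l <- pick(with, "level")
  gl <- pick(with, "group:level")
  dfB <- betw[match("Residuals", rn(betw)), "Df"]
  dfW <- with[match("Residuals", rn(with)), "Df"]
  ssB <- betw[match("Residuals", rn(betw)), "Sum Sq"]
  ssW <- with[match("Residuals", rn(with)), "Sum Sq"]
  res <- data.frame(
    effect = c("group", "within", "interaction"),
    ss = c(g["ss"], l["ss"], gl["ss"]),
    df1 = c(g["df"], l["df"], gl["df"]),
    df2 = c(dfB, dfW, dfW),
    F = c(g["F"], l["F"], gl["F"]),
    p = c(g["p"], l["p"], gl["p"]),
    stratum = c("subject", "subject:level", "subject:level"),
    stringsAsFactors = FALSE)
  ## a zero-variance table has SS = 0 everywhere: report F = 0, p = 1
  degenerate <- res$ss < .Machine$double.eps * 100
  res$F[degenerate] <- 0
  res$p[degenerate] <- 1
  rownames(res) <- res$effect
  new("AnovaResult", table = res,
      strata = c(subject = ssB, `subject:level` = ssW), species = species)
}

setMethod("show", "AnovaResult", function(object) {
  cat("Mixed rm-ANOVA (", object@species, "):\n", sep = "")
  t <- object@table
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-12s F(%d, %d) = %.4g, p = %.4g\n", t$effect[i],
                t$df1[i], t$df2[i], t$F[i], t$p[i]))
})

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level (0 < alpha < 1).
#' @param m number of comparisons (>= 1).
#' @return alpha / m.
#' @examples
#' bonferroniThreshold(0.05, 15)  # ~0.0033, the working level 0.003
#' @export
bonferroniThreshold <- function(alpha, m) {
  stopifnot(m >= 1, alpha > 0, alpha < 1)
  alpha / m
}

#' Two-sample equal-variance t-test
#'
#' Pooled-variance t statistic with df = n_a + n_b - 2 and a two-tailed p
#' value. A zero pooled variance with unequal means is reported as an
#' infinite-t case (p = 0) rather than an error; equal constant samples
#' give t = 0, p = 1.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list(t, df, p).
#' @export
tTestTwoSampleEqualVar <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  df <- length(a) + length(b) - 2
  pooled <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) / df
  if (pooled == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1))
    message("tTestTwoSampleEqualVar: zero pooled variance with unequal ",
            "means; reporting infinite t")
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Mean hypercapnia response magnitude
#'
#' Mean fractional deviation from baseline over the response window
#' (default 250-500 s after record start).
#'
#' @param series fractional concentration series (1 = baseline).
#' @param rateHz sampling rate.
#' @param windowS c(start, end) seconds.
#' @return scalar mean fractional deviation.
#' @export
hypercapniaMagnitude <- function(series, rateHz, windowS = c(250, 500)) {
  idx <- seq(floor(windowS[1] * rateHz) + 1, floor(windowS[2] * rateHz))
  if (max(idx) > length(series))
    stop("record too short: need ", windowS[2], " s of data")
  mean(series[idx] - 1)
}

#' Simulate a cohort magnitude table
#'
#' Draws per-subject response magnitudes around true per-level values with
#' a between-subject random effect and residual noise — the magnitude-level
#' cohort generator used for ANOVA calibration (type-I rate and power)
#' studies. A non-zero \code{groupDeficit} is subtracted from every "ad"
#' subject's magnitudes, emulating the acute-scenario deficit.
#'
#' @param nPerGroup subjects per group.
#' @param trueMagnitudes named numeric vector of per-level true fractional
#'   magnitudes; defaults to plausible evoked Hbt magnitudes for the five
#'   stimulation experiments.
#' @param groupDeficit magnitude subtracted for the "ad" group (0 = null).
#' @param subjectSd between-subject SD.
#' @param residualSd residual SD.
#' @param seed integer seed.
#' @param species label written into the table.
#' @return long-format data.frame (see \code{\link{longTable}}).
#' @export
simulateCohortMagnitudes <- function(nPerGroup = 5,
                                     trueMagnitudes = c(Exp1 = 0.020,
                                                        Exp2 = 0.020,
                                                        Exp4 = 0.018,
                                                        Exp5 = 0.035,
                                                        Exp7 = 0.040),
                                     groupDeficit = 0,
                                     subjectSd = 0.002,
                                     residualSd = 0.004,
                                     seed = 1, species = "Hbt") {
  set.seed(as.integer(seed))
  rows <- list()
  for (grp in c("wt", "ad")) {
    for (s in seq_len(nPerGroup)) {
      sid <- paste0(grp, s)
      re <- rnorm(1, 0, subjectSd)
      mag <- trueMagnitudes + re +
        rnorm(length(trueMagnitudes), 0, residualSd) -
        if (grp == "ad") groupDeficit else 0
      rows[[length(rows) + 1]] <- longTable(sid, grp,
                                            names(trueMagnitudes),
                                            species, mag)
    }
  }
  do.call(rbind, rows)
}
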