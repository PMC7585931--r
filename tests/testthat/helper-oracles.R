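# Independent brute-force sums-of-squares decomposition for the mixed
# two-way design (between: group, within: level). Used as the oracle for
# the rm-ANOVA implementation; deliberately written from the textbook
# cell-mean formulas, not via model fitting.
bruteForceAnova <- function(d) {
  d$subject <- factor(d$subject); d$group <- factor(d$group)
  d$level <- factor(d$level)
  gm <- mean(d$magnitude)
  nS <- nlevels(d$subject); nL <- nlevels(d$level)
  subjMean <- tapply(d$magnitude, d$subject, mean)
  groupMean <- tapply(d$magnitude, d$group, mean)
  levelMean <- tapply(d$magnitude, d$level, mean)
  cellMean <- tapply(d$magnitude, list(d$group, d$level), mean)
  groupOf <- tapply(as.character(d$group), d$subject, unique)
  nPerGroup <- table(groupOf)

  ssGroup <- sum(nPerGroup * nL * (groupMean[names(nPerGroup)] - gm)^2)
  ssSubj <- nL * sum((subjMean - groupMean[groupOf])^2)
  ssLevel <- nS * sum((levelMean - gm)^2)
  ssCell <- 0
  for (g in levels(d$group)) for (l in levels(d$level)) {
    n <- nPerGroup[[g]]
    ssCell <- ssCell + n * (cellMean[g, l] - groupMean[[g]] -
                              levelMean[[l]] + gm)^2
  }
  ssTot <- sum((d$magnitude - gm)^2)
  ssRes <- ssTot - ssGroup - ssSubj - ssLevel - ssCell
  dfG <- nlevels(d$group) - 1; dfS <- nS - nlevels(d$group)
  dfL <- nL - 1; dfI <- dfG * dfL; dfR <- dfS * dfL
  list(F = c(group = (ssGroup / dfG) / (ssSubj / dfS),
             within = (ssLevel / dfL) / (ssRes / dfR),
             interaction = (ssCell / dfI) / (ssRes / dfR)),
       ss = c(group = ssGroup, subject = ssSubj, within = ssLevel,
              interaction = ssCell, residual = ssRes, total = ssTot))
}
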