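# Automated group statistics over quantification results
# (module: group_statistics). Nonparametric tests carry exact small-sample
# paths (full enumeration / permutation distributions); base R
# implementations serve as cross-checks in the test-suite, not as the
# implementation, since the exact paths specified here are not all exposed
# there.

#' Select the statistical test plan
#'
#' Nonparametric tests for n per group < 30, parametric otherwise; paired
#' two-group designs use the signed-rank test, paired multi-group designs
#' the Friedman omnibus with signed-rank post hoc; unpaired analogues are
#' the rank-sum test and Kruskal-Wallis; the parametric branch uses t tests
#' and (repeated-measures) ANOVA.
#'
#' @param nPerGroup number of animals per group.
#' @param paired logical.
#' @param nGroups number of experimental groups (>= 2).
#' @return list (a StatPlan): n_per_group, paired, n_groups, family,
#'   omnibus_test, posthoc_test.
#' @export
selectTest <- function(nPerGroup, paired, nGroups) {
  if (nGroups < 2L) stop("need at least two groups")
  if (nPerGroup < 2L) stop("need at least two observations per group")
  family <- if (nPerGroup < 30) "nonparametric" else "parametric"
  if (family == "nonparametric") {
    if (paired) {
      omnibus <- if (nGroups == 2L) "wilcoxon_signed_rank" else "friedman"
      posthoc <- if (nGroups > 2L) "wilcoxon_signed_rank" else "none"
    } else {
      omnibus <- if (nGroups == 2L) "wilcoxon_rank_sum" else "kruskal_wallis"
      posthoc <- if (nGroups > 2L) "wilcoxon_rank_sum" else "none"
    }
  } else {
    if (paired) {
      omnibus <- if (nGroups == 2L) "paired_t" else "repeated_measures_anova"
      posthoc <- if (nGroups > 2L) "paired_t" else "none"
    } else {
      omnibus <- if (nGroups == 2L) "two_sample_t" else "one_way_anova"
      posthoc <- if (nGroups > 2L) "two_sample_t" else "none"
    }
  }
  list(n_per_group = nPerGroup, paired = paired, n_groups = nGroups,
       family = family, omnibus_test = omnibus, posthoc_test = posthoc)
}

midRank <- function(x) rank(x, ties.method = "average")

#' Friedman test for paired multi-group designs
#'
#' Within-subject mid-ranks; the tie-corrected chi-square statistic with
#' k - 1 degrees of freedom. For small designs (subjects <= exactLimit and
#' <= 4 groups) the exact permutation p-value over all within-subject rank
#' permutations is computed by convolution and returned alongside.
#'
#' @param values numeric matrix, subjects x groups, no missing cells.
#' @param exactLimit maximum subject count for the exact path (default 8).
#' @return list(statistic, df, p_value, p_exact (or NA), method).
#' @export
friedmanTest <- function(values, exactLimit = 8L) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("missing cells are not allowed")
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 groups")
  R <- t(apply(values, 1, midRank))
  Rj <- colSums(R)
  # tie correction per subject
  ties <- apply(values, 1, function(r) {
    tt <- table(r); sum(tt^3 - tt)
  })
  C <- 1 - sum(ties) / (n * k * (k^2 - 1))
  stat0 <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  statistic <- if (C > 0) stat0 / C else 0
  p <- stats::pchisq(statistic, df = k - 1, lower.tail = FALSE)
  pExact <- NA_real_
  if (n <= exactLimit && k <= 4L) {
    pExact <- friedmanExactP(R, statistic, C)
  }
  list(statistic = statistic, df = k - 1, p_value = p, p_exact = pExact,
       method = "Friedman chi-square (tie-corrected)")
}

# exact permutation distribution of the Friedman statistic by convolution
# over subjects: each subject's observed rank vector is permuted over all
# k! column orders; the statistic depends only on column rank sums.
friedmanExactP <- function(R, observed, C) {
  n <- nrow(R); k <- ncol(R)
  perms <- permMatrix(k)
  # state: distribution over rank-sum vectors (scaled by 2 to keep integers
  # with mid-ranks)
  enc <- function(v) paste(v, collapse = ",")
  dist <- stats::setNames(1, enc(numeric(k)))
  for (i in seq_len(n)) {
    r2 <- 2 * R[i, ]
    newDist <- new.env(parent = emptyenv())
    for (s in names(dist)) {
      base <- as.numeric(strsplit(s, ",")[[1]])
      w <- dist[[s]]
      for (p in seq_len(nrow(perms))) {
        v <- base + r2[perms[p, ]]
        key <- enc(v)
        prev <- newDist[[key]]
        newDist[[key]] <- if (is.null(prev)) w else prev + w
      }
    }
    keys <- ls(newDist)
    dist <- stats::setNames(vapply(keys, function(kk) newDist[[kk]],
                                   numeric(1)), keys)
  }
  total <- sum(dist)
  cnt <- 0
  for (s in names(dist)) {
    Rj <- as.numeric(strsplit(s, ",")[[1]]) / 2
    stat0 <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
    st <- if (C > 0) stat0 / C else 0
    if (st >= observed - 1e-9) cnt <- cnt + dist[[s]]
  }
  cnt / total
}

permMatrix <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permMatrix(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; absolute differences receive mid-ranks.
#' Exact two-sided p by full sign enumeration for n <= exactLimit (default
#' 15); otherwise the normal approximation with continuity correction and
#' tie correction. All-zero differences give the degenerate p = 1 with a
#' flag.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @param exactLimit enumeration cap.
#' @return list(statistic (V = sum of positive ranks), n_effective,
#'   p_value, exact, degenerate).
#' @export
wilcoxonSignedRank <- function(x, y, exactLimit = 15L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, n_effective = 0L, p_value = 1,
                exact = TRUE, degenerate = TRUE))
  r <- midRank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exactLimit) {
    # enumerate all 2^n sign assignments of the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.vector(signs %*% r)
    pGe <- mean(Vs >= V - 1e-9)
    pLe <- mean(Vs <= V + 1e-9)
    p <- min(1, 2 * min(pGe, pLe))
    return(list(statistic = V, n_effective = n, p_value = p, exact = TRUE,
                degenerate = FALSE))
  }
  mu <- n * (n + 1) / 4
  tt <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = V, n_effective = n, p_value = p, exact = FALSE,
       degenerate = FALSE)
}

#' Wilcoxon rank-sum test for two independent samples
#'
#' Exact two-sided p by enumerating all group-label assignments when the
#' combined sample size is at most \code{exactLimit} (default 20) and there
#' are no cross-group ties; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param exactLimit combined-size cap for the exact path.
#' @return list(statistic (W = rank sum of x minus its minimum, the
#'   Mann-Whitney U), p_value, exact).
#' @export
wilcoxonRankSum <- function(x, y, exactLimit = 20L) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both samples must be nonempty")
  all <- c(x, y)
  r <- midRank(all)
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  hasTies <- anyDuplicated(all) > 0
  if (nx + ny <= exactLimit && !hasTies) {
    combos <- utils::combn(nx + ny, nx)
    Ws <- colSums(matrix(r[combos], nrow = nx))
    pGe <- mean(Ws >= W - 1e-9)
    pLe <- mean(Ws <= W + 1e-9)
    p <- min(1, 2 * min(pGe, pLe))
    return(list(statistic = U, p_value = p, exact = TRUE))
  }
  N <- nx + ny
  mu <- nx * ny / 2
  tt <- table(all)
  sig2 <- nx * ny / 12 * (N + 1 - sum(tt^3 - tt) / (N * (N - 1)))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = U, p_value = p, exact = FALSE)
}

#' Normality diagnostics for one group of values
#'
#' Shapiro-Wilk and Anderson-Darling p-values plus theoretical-vs-sample
#' quantile pairs for QQ plotting.
#'
#' @param values numeric vector, n >= 3, non-constant.
#' @return list(shapiro_p, anderson_p, qq_points = data.frame(theoretical,
#'   sample)).
#' @export
normalityDiagnostics <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("need at least 3 values")
  if (stats::sd(values) == 0) stop("constant input")
  sw <- stats::shapiro.test(values)
  ad <- if (length(values) >= 8L) nortest::ad.test(values)
        else list(p.value = NA_real_) # AD needs n >= 8
  qq <- stats::qqnorm(values, plot.it = FALSE)
  list(shapiro_p = sw$p.value, anderson_p = ad$p.value,
       qq_points = data.frame(theoretical = sort(qq$x),
                              sample = sort(qq$y)))
}

runOmnibus <- function(mat, plan) {
  k <- ncol(mat)
  switch(plan$omnibus_test,
    friedman = { f <- friedmanTest(mat)
                 list(statistic = f$statistic, p = f$p_value) },
    wilcoxon_signed_rank = { w <- wilcoxonSignedRank(mat[, 1], mat[, 2])
                             list(statistic = w$statistic, p = w$p_value) },
    wilcoxon_rank_sum = { w <- wilcoxonRankSum(mat[, 1], mat[, 2])
                          list(statistic = w$statistic, p = w$p_value) },
    kruskal_wallis = { kw <- stats::kruskal.test(
                         as.vector(mat),
                         factor(rep(colnames(mat), each = nrow(mat))))
                       list(statistic = unname(kw$statistic),
                            p = kw$p.value) },
    paired_t = { tt <- stats::t.test(mat[, 1], mat[, 2], paired = TRUE)
                 list(statistic = unname(tt$statistic), p = tt$p.value) },
    two_sample_t = { tt <- stats::t.test(mat[, 1], mat[, 2])
                     list(statistic = unname(tt$statistic), p = tt$p.value) },
    repeated_measures_anova = {
      df <- data.frame(y = as.vector(mat),
                       g = factor(rep(seq_len(k), each = nrow(mat))),
                       s = factor(rep(seq_len(nrow(mat)), k)))
      fit <- stats::aov(y ~ g + Error(s), data = df)
      sm <- summary(fit)[["Error: Within"]][[1]]
      list(statistic = sm[["F value"]][1], p = sm[["Pr(>F)"]][1])
    },
    one_way_anova = {
      df <- data.frame(y = as.vector(mat),
                       g = factor(rep(seq_len(k), each = nrow(mat))))
      fit <- stats::aov(y ~ g, data = df)
      sm <- summary(fit)[[1]]
      list(statistic = sm[["F value"]][1], p = sm[["Pr(>F)"]][1])
    },
    stop("unknown omnibus test: ", plan$omnibus_test))
}

runPosthoc <- function(mat, plan) {
  if (plan$posthoc_test == "none") return(NULL)
  grp <- colnames(mat)
  prs <- utils::combn(ncol(mat), 2)
  out <- lapply(seq_len(ncol(prs)), function(i) {
    a <- prs[1, i]; b <- prs[2, i]
    p <- switch(plan$posthoc_test,
      wilcoxon_signed_rank = wilcoxonSignedRank(mat[, a], mat[, b])$p_value,
      wilcoxon_rank_sum = wilcoxonRankSum(mat[, a], mat[, b])$p_value,
      paired_t = stats::t.test(mat[, a], mat[, b], paired = TRUE)$p.value,
      two_sample_t = stats::t.test(mat[, a], mat[, b])$p.value)
    data.frame(pair = paste(grp[a], grp[b], sep = "-"), p_value = p)
  })
  do.call(rbind, out)
}

#' Automated per-region group statistics with plots
#'
#' For every region x interval x parameter the test plan is selected from
#' the design, the omnibus test (and post hoc pairs when more than two
#' groups) is run, normality diagnostics are computed per group, and
#' boxplots with individual animal values plus QQ plots are written. No
#' multiple-testing correction is applied across regions by default; Holm
#' correction is available behind \code{adjust}.
#'
#' @param quant a \code{\linkS4class{QuantResult}}.
#' @param paired logical: are the states/groups paired within animal?
#' @param groupBy column defining the compared groups: \code{"state"}
#'   (default, longitudinal designs) or \code{"group"}.
#' @param parameters which parameters to analyse (default all three).
#' @param plotDir directory for plot files, or NULL to skip plotting.
#' @param adjust p-adjustment across regions: \code{"none"} (default) or
#'   \code{"holm"}.
#' @return data.frame: region, interval, parameter, test, statistic,
#'   p_value, posthoc (list column as JSON string), plus per-group
#'   normality p-values.
#' @export
runRegionStats <- function(quant, paired = TRUE, groupBy = c("state", "group"),
                           parameters = c("A_N", "SUV", "UR"),
                           plotDir = NULL, adjust = c("none", "holm")) {
  groupBy <- match.arg(groupBy)
  adjust <- match.arg(adjust)
  tab <- quant@table
  groups <- unique(tab[[groupBy]])
  if (length(groups) < 2L) stop("need at least two groups")
  if (!is.null(plotDir) && !dir.exists(plotDir))
    dir.create(plotDir, recursive = TRUE)
  out <- list()
  for (region in unique(tab$region)) for (interval in unique(tab$interval))
    for (param in parameters) {
      sub <- tab[tab$region == region & tab$interval == interval, ]
      wide <- tryCatch(
        stats::reshape(sub[c("animal_id", groupBy, param)],
                       idvar = "animal_id", timevar = groupBy,
                       direction = "wide"),
        error = function(e) NULL)
      if (is.null(wide)) next
      mat <- as.matrix(wide[, -1, drop = FALSE])
      colnames(mat) <- sub(paste0("^", param, "\\."), "", colnames(mat))
      if (paired && any(!is.finite(mat))) {
        warning("region ", region, " skipped: missing animals in paired design")
        next
      }
      plan <- selectTest(nrow(mat), paired, ncol(mat))
      om <- runOmnibus(mat, plan)
      ph <- runPosthoc(mat, plan)
      norm <- lapply(seq_len(ncol(mat)), function(j) {
        tryCatch(normalityDiagnostics(mat[, j])[c("shapiro_p", "anderson_p")],
                 error = function(e) list(shapiro_p = NA_real_,
                                          anderson_p = NA_real_))
      })
      if (!is.null(plotDir))
        emitStatPlots(mat, region, interval, param, plotDir)
      out[[length(out) + 1L]] <- data.frame(
        region = region, interval = interval, parameter = param,
        test = plan$omnibus_test, statistic = om$statistic,
        p_value = om$p,
        posthoc = if (is.null(ph)) NA_character_ else
          jsonlite::toJSON(ph, digits = NA),
        min_shapiro_p = min(vapply(norm, `[[`, numeric(1), "shapiro_p")),
        stringsAsFactors = FALSE)
    }
  res <- do.call(rbind, out)
  if (adjust == "holm" && !is.null(res))
    res$p_adjusted <- stats::p.adjust(res$p_value, "holm")
  res
}

emitStatPlots <- function(mat, region, interval, param, plotDir) {
  stem <- file.path(plotDir,
                    gsub("[^A-Za-z0-9_.-]", "_",
                         paste(region, interval, param, sep = "_")))
  devices <- list(png = function(f) grDevices::png(f, 900, 700, res = 120))
  if (isTRUE(capabilities("cairo")))
    devices$svg <- function(f) grDevices::svg(f, 7, 5.5)
  for (ext in names(devices)) {
    f <- paste0(stem, "_boxplot.", ext)
    ok <- tryCatch({ devices[[ext]](f); TRUE }, error = function(e) FALSE)
    if (!ok) next
    graphics::boxplot(mat, ylab = param,
                      main = paste(region, interval))
    for (j in seq_len(ncol(mat)))
      graphics::points(jitter(rep(j, nrow(mat)), amount = 0.08), mat[, j],
                       pch = 19, col = "#00000080")
    grDevices::dev.off()
    f <- paste0(stem, "_qq.", ext)
    ok <- tryCatch({ devices[[ext]](f); TRUE }, error = function(e) FALSE)
    if (!ok) next
    old <- graphics::par(mfrow = c(1, ncol(mat)))
    for (j in seq_len(ncol(mat))) {
      stats::qqnorm(mat[, j], main = colnames(mat)[j])
      stats::qqline(mat[, j])
    }
    graphics::par(old)
    grDevices::dev.off()
  }
  invisible(NULL)
}
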