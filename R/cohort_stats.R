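# Cohort-level statistics: zero-inflated negative binomial enrichment of
# per-sample MEI counts by group (tumor type), endonuclease-motif feature
# binning of the genome with negative-binomial enrichment regression,
# per-window insertion-rate tracks, Mann-Whitney group tests with BH
# correction, and Spearman correlation of MEI vs structural-variant
# burden.

#' Zero-inflated negative binomial enrichment of a sample group
#'
#' Fits, by direct maximum likelihood, a two-part model to per-sample MEI
#' counts: a logistic zero-inflation component and a negative binomial
#' count component, both with a binary covariate indicating membership of
#' `target_group`. The count-component group coefficient's Wald z and p
#' quantify enrichment (z > 0) or depletion (z < 0) of the group relative
#' to the rest of the cohort. Starting values are method-of-moments; the
#' optimizer is deterministic.
#'
#' @param counts data.frame with `sample_id`, `group_label`, `mei_count`.
#' @param target_group the group tested against all others.
#' @param min_group_size minimum samples in the target group (default 15).
#' @return list: z, p, direction, coefficients (count intercept/group,
#'   zero intercept/group, log_theta), converged.
#' @export
zinb_enrichment <- function(counts, target_group, min_group_size = 15L) {
  y <- counts$mei_count
  x <- as.integer(counts$group_label == target_group)
  if (sum(x) < min_group_size)
    stop("target group has fewer than ", min_group_size, " samples")
  if (all(y[x == 1] == 0)) stop("all-zero target group: model degenerate")
  fit <- zinb_fit(y, x)
  if (!fit$converged)
    stop("ZINB fit did not converge: ", fit$message)
  z <- fit$coef["count_group"] / fit$se["count_group"]
  p <- 2 * pnorm(-abs(z))
  list(z = unname(z), p = unname(p),
       direction = if (z >= 0) "enriched" else "depleted",
       coefficients = fit$coef, se = fit$se, converged = TRUE,
       loglik = fit$loglik)
}

# direct ML fit of the two-part model; returns coef, se (from numerical
# Hessian), loglik
zinb_fit <- function(y, x) {
  nll <- function(par) {
    b0 <- par[1]; b1 <- par[2]      # count: log mu
    g0 <- par[3]; g1 <- par[4]      # zero: logit pi
    lt <- par[5]                    # log theta
    mu <- exp(b0 + b1 * x)
    pi0 <- plogis(g0 + g1 * x)
    th <- exp(lt)
    dnb <- dnbinom(y, size = th, mu = mu)
    ll <- ifelse(y == 0,
                 log(pi0 + (1 - pi0) * dnb + 1e-300),
                 log(1 - pi0 + 1e-300) + dnbinom(y, size = th, mu = mu, log = TRUE))
    -sum(ll)
  }
  # method-of-moments starts on the positive part
  ypos <- y[y > 0]
  mu0 <- max(mean(ypos), 0.5)
  v0 <- max(var(ypos), mu0 + 0.1)
  th0 <- max(mu0^2 / max(v0 - mu0, 0.1), 0.05)
  p00 <- min(max(mean(y == 0) - dnbinom(0, mu = mu0, size = th0), 0.01), 0.95)
  start <- c(log(mu0), 0, qlogis(p00), 0, log(th0))
  opt <- optim(start, nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-10))
  se <- rep(NA_real_, 5)
  ok <- opt$convergence == 0
  if (ok) {
    h <- tryCatch(solve(opt$hessian), error = function(e) NULL)
    if (is.null(h) || any(!is.finite(diag(h))) || any(diag(h) <= 0)) ok <- FALSE
    else se <- sqrt(diag(h))
  }
  nm <- c("count_intercept", "count_group", "zero_intercept", "zero_group",
          "log_theta")
  list(coef = setNames(opt$par, nm), se = setNames(se, nm),
       loglik = -opt$value, converged = ok,
       message = if (ok) "" else "optim/Hessian failure")
}

#' Endonuclease-motif closeness track from a reference
#'
#' Per-position minimum Hamming distance of either strand to the L1
#' endonuclease 5-mer motif (TTTT|R; equivalently Y|AAAA on the other
#' strand), binned as >= 4 mismatches -> bin 0, 3 -> 1, 2 -> 2,
#' <= 1 -> 3.
#'
#' @param ref_seqs named contig sequences.
#' @return list per contig of integer bin vectors (position = 5-mer
#'   start, 0-based), plus `footprint_bp` per bin; class `feature_track`.
#' @export
motif_track_from_reference <- function(ref_seqs) {
  bins <- lapply(ref_seqs, function(s) {
    n <- nchar(s)
    if (n < 5) return(integer(0))
    x <- strsplit(toupper(s), "")[[1]]
    shift <- function(k) x[k:(n - 5 + k)]
    s1 <- shift(1); s2 <- shift(2); s3 <- shift(3); s4 <- shift(4); s5 <- shift(5)
    mm_for <- function(p1, p2, p3, p4, p5) {
      (!s1 %in% p1) + (!s2 %in% p2) + (!s3 %in% p3) + (!s4 %in% p4) + (!s5 %in% p5)
    }
    mm <- pmin(
      mm_for("T", "T", "T", "T", c("A", "G")),      # TTTTR (+)
      mm_for(c("C", "T"), "A", "A", "A", "A"))      # YAAAA (rev. comp. strand)
    bin <- integer(length(mm))
    bin[mm >= 4] <- 0L; bin[mm == 3] <- 1L; bin[mm == 2] <- 2L; bin[mm <= 1] <- 3L
    bin
  })
  fp <- tabulate(unlist(bins) + 1L, nbins = 4L)
  structure(list(bins = bins, footprint_bp = setNames(fp, 0:3)),
            class = "feature_track")
}

#' Insertion counts per fixed genomic window
#'
#' Fixed non-overlapping tiling; insertions are assigned by their
#' 3'-breakpoint position with the half-open convention (a breakpoint at
#' k * window goes to the right window).
#'
#' @param insertions data.frame with chrom and pos (0-based).
#' @param contig_lengths named lengths.
#' @param window window size in bp (default 1e6).
#' @return data.frame chrom/start/end/count covering every contig.
#' @export
rate_per_window <- function(insertions, contig_lengths, window = 1000000L) {
  out <- NULL
  for (ch in names(contig_lengths)) {
    L <- contig_lengths[[ch]]
    starts <- seq(0L, L - 1L, by = window)
    ends <- pmin(starts + window, L)
    cnt <- integer(length(starts))
    if (!is.null(insertions) && nrow(insertions)) {
      p <- insertions$pos[insertions$chrom == ch]
      if (length(p)) {
        idx <- p %/% window + 1L
        tab <- table(idx)
        cnt[as.integer(names(tab))] <- as.integer(tab)
      }
    }
    out <- rbind(out, data.frame(chrom = ch, start = starts, end = ends,
                                 count = cnt, stringsAsFactors = FALSE))
  }
  out
}

#' Per-bin enrichment of insertion rate over a feature track
#'
#' Negative binomial regression of per-window insertion counts on the
#' target track's bin indicators (plus optional covariate-track
#' indicators) with a log-footprint offset. Enrichment of bins 1-3 is
#' reported as fold change versus bin 0, which is fixed at 1 by
#' construction; Wald 95% CIs accompany each estimate.
#'
#' @param insertion_positions data.frame chrom/pos.
#' @param track `feature_track` for the target feature.
#' @param covariate_tracks list of additional `feature_track`s to adjust
#'   for.
#' @param window analysis window in bp (default 10000).
#' @param contig_lengths named contig lengths (defaults to track extent).
#' @return data.frame bin/enrichment/ci_lo/ci_hi (bin 0 row = 1).
#' @export
feature_association <- function(insertion_positions, track,
                                covariate_tracks = list(), window = 10000L,
                                contig_lengths = NULL) {
  if (is.null(contig_lengths))
    contig_lengths <- vapply(track$bins, length, 1L) + 4L
  # analysis cells: (window x target bin), each with its bp footprint, the
  # count of insertions falling on positions of that bin, and the modal
  # covariate bin over those positions
  rows <- NULL
  for (ch in names(track$bins)) {
    bb_all <- track$bins[[ch]]
    L <- contig_lengths[[ch]]
    starts <- seq(0L, L - 1L, by = window)
    ip <- if (is.null(insertion_positions)) integer(0)
    else insertion_positions$pos[insertion_positions$chrom == ch]
    ip <- ip[ip + 1L <= length(bb_all)]
    ib <- bb_all[ip + 1L]  # bin at each insertion position
    for (si in seq_along(starts)) {
      s <- starts[si]; e <- min(s + window, L)
      idx <- (s + 1L):min(e, length(bb_all))
      if (length(idx) < 10) next
      bb <- bb_all[idx]
      in_w <- ip >= s & ip < e
      for (b in 0:3) {
        fp <- sum(bb == b)
        if (fp == 0) next
        row <- data.frame(count = sum(in_w & ib == b), footprint = fp,
                          bin = as.character(b), stringsAsFactors = FALSE)
        for (ci in seq_along(covariate_tracks)) {
          cb <- covariate_tracks[[ci]]$bins[[ch]][idx][bb == b]
          row[[paste0("cov", ci)]] <-
            names(sort(table(cb), decreasing = TRUE))[1]
        }
        rows <- rbind(rows, row)
      }
    }
  }
  rows$bin <- factor(rows$bin, levels = as.character(0:3))
  form <- "count ~ bin + offset(log(footprint))"
  for (ci in seq_along(covariate_tracks)) {
    rows[[paste0("cov", ci)]] <- factor(rows[[paste0("cov", ci)]],
                                        levels = as.character(0:3))
    form <- paste0(form, " + cov", ci)
  }
  fit <- tryCatch(
    MASS::glm.nb(stats::as.formula(form), data = rows),
    error = function(e) stats::glm(stats::as.formula(form),
                                   family = stats::poisson(), data = rows))
  cf <- coef(summary(fit))
  out <- data.frame(bin = 0:3, enrichment = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_)
  out$enrichment[1] <- 1; out$ci_lo[1] <- 1; out$ci_hi[1] <- 1
  for (b in 1:3) {
    nm <- paste0("bin", b)
    if (nm %in% rownames(cf)) {
      est <- cf[nm, "Estimate"]; se <- cf[nm, "Std. Error"]
      out$enrichment[b + 1] <- exp(est)
      out$ci_lo[b + 1] <- exp(est - 1.96 * se)
      out$ci_hi[b + 1] <- exp(est + 1.96 * se)
    }
  }
  out
}

#' Mann-Whitney group comparison of MEI counts with BH correction
#'
#' Two-sided Mann-Whitney U tests of `mei_count` between the two levels of
#' each grouping (e.g. mutated vs non-mutated tumor-suppressor gene),
#' Benjamini-Hochberg adjusted across the family; adjusted P < 0.05 is
#' flagged significant.
#'
#' @param counts data.frame with `sample_id` and `mei_count`.
#' @param groupings named list; each element is a logical/character vector
#'   (parallel to `counts` rows) with exactly two groups.
#' @return data.frame test/U/p/q/significant.
#' @export
group_test <- function(counts, groupings) {
  res <- NULL
  for (nm in names(groupings)) {
    g <- groupings[[nm]]
    lv <- unique(g)
    if (length(lv) != 2 || any(table(g) == 0))
      stop("grouping '", nm, "' must have two non-empty groups")
    a <- counts$mei_count[g == lv[1]]
    b <- counts$mei_count[g == lv[2]]
    wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
    res <- rbind(res, data.frame(test = nm, U = unname(wt$statistic),
                                 p = wt$p.value, stringsAsFactors = FALSE))
  }
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$q < 0.05
  res
}

#' Spearman correlation of MEI and structural-variant burden
#'
#' @param counts data.frame with `mei_count` and `sv_count`.
#' @return list(rho, p, n) or NULL (with a warning) for constant input.
#' @export
sv_correlation <- function(counts) {
  ok <- complete.cases(counts[, c("mei_count", "sv_count")])
  x <- counts$mei_count[ok]; y <- counts$sv_count[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant vector: correlation undefined")
    return(NULL)
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
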