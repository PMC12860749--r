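# Independent brute-force oracles. These deliberately use plain loops and
# direct transcriptions of the published rules, not the package's vectorized
# implementations, so that agreement is a genuine dual-route check.

# cCTv by an explicit per-voxel loop (default "density" interpretation)
oracle_cctv <- function(ct, working_mask) {
  vx <- prod(ct$spacing)
  cum_hu <- 0
  n_mm <- 0L
  n_cav <- 0L
  idx <- which(working_mask$data)
  for (i in idx) {
    n_cav <- n_cav + 1L
    hu <- ct$data[i]
    if (hu > -30 && hu <= 120) {
      cum_hu <- cum_hu + hu
      n_mm <- n_mm + 1L
    }
  }
  if (n_mm == 0L) return(0)
  (cum_hu * vx) / (n_cav * vx)
}

# VOI stats by explicit accumulation
oracle_voi_stats <- function(suv, mask) {
  vals <- c()
  for (i in which(mask$data)) vals <- c(vals, suv$data[i])
  list(suv_max = max(vals), suv_mean = sum(vals) / length(vals),
       suv_median = stats::median(vals),
       volume_ml = length(vals) * prod(suv$spacing) / 1000)
}

# MTV/TLG by explicit loop
oracle_mtv_tlg <- function(suv, mask, thr) {
  n <- 0L; s <- 0
  for (i in which(mask$data)) {
    if (suv$data[i] >= thr) { n <- n + 1L; s <- s + suv$data[i] }
  }
  mtv <- n * prod(suv$spacing) / 1000
  list(mtv_ml = mtv, tlg_g = if (n > 0) (s / n) * mtv else 0)
}

# exhaustive manual-CTv sweep: loop over every center and disc offset
oracle_manual_ctv <- function(ct, working_mask, radii_mm, axis = 3L) {
  shp <- dim(ct$data)
  sp <- ct$spacing
  plane <- setdiff(1:3, axis)
  best <- -Inf
  for (r in radii_mm) {
    m1 <- floor(r / sp[plane[1]]); m2 <- floor(r / sp[plane[2]])
    offs <- list()
    for (d1 in -m1:m1) for (d2 in -m2:m2)
      if ((d1 * sp[plane[1]])^2 + (d2 * sp[plane[2]])^2 <= r^2 + 1e-9)
        offs[[length(offs) + 1]] <- c(d1, d2)
    for (lin in which(working_mask$data)) {
      cidx <- arrayInd(lin, shp)[1, ]
      tot <- 0; ok <- TRUE
      for (o in offs) {
        p <- cidx
        p[plane[1]] <- p[plane[1]] + o[1]
        p[plane[2]] <- p[plane[2]] + o[2]
        if (any(p < 1) || any(p > shp) ||
            !working_mask$data[p[1], p[2], p[3]]) { ok <- FALSE; break }
        tot <- tot + ct$data[p[1], p[2], p[3]]
      }
      if (ok) best <- max(best, tot / length(offs))
    }
  }
  if (!is.finite(best)) stop("no ROI fits")
  best
}

# literal transcription of the printed five-point scale, with the documented
# convention that the unassigned gap (L, 1.1 L] scores 3
oracle_deauville <- function(t, m, l) {
  if (t == 0) return(1L)            # score 1: no uptake at all
  if (t <= m) return(2L)            # score 2: <= mediastinal blood pool
  if (t <= l) return(3L)            # score 3: > mediastinum, <= liver
  if (t <= 1.1 * l) return(3L)      # documented gap convention
  if (t <= 2 * l) return(4L)        # score 4: > liver + 10%
  5L                                # score 5: >> liver (twice)
}

# exact two-sided rank-sum p by enumerating every assignment of ranks
oracle_ranksum_p <- function(a, b) {
  vals <- c(a, b)
  stopifnot(!any(duplicated(vals)))
  n1 <- length(a)
  rk <- rank(vals)
  w_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(vals), n1)
  ws <- apply(combs, 2, function(ix) sum(rank(vals)[ix]) -
                n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_signedrank_p <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12, !any(duplicated(abs(d))))
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- apply(signs, 1, function(s) sum(rk[s]))
  mean(abs(vs - mu) >= abs(v_obs - mu))
}

# Kruskal-Wallis H from the textbook rank formula (no ties assumed)
oracle_kruskal_h <- function(values, group) {
  stopifnot(!any(duplicated(values)))
  n <- length(values)
  rk <- rank(values)
  h <- 0
  for (g in unique(group)) {
    sel <- group == g
    h <- h + sum(rk[sel])^2 / sum(sel)
  }
  12 / (n * (n + 1)) * h - 3 * (n + 1)
}

# Pearson chi-square by hand from a count matrix
oracle_chisq <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

# Cohen's kappa closed form from a confusion matrix
oracle_kappa <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}
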