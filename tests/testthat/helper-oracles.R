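# Independent brute-force oracles, written as literal loops over the
# definitions. They intentionally share no code with the package internals
# (different traversal, different formula organisation) so that agreement is
# evidence of correctness rather than of shared bugs.

# Build a discretized_volume-compatible object straight from an integer
# gray-level array (NA outside the VOI); continuous values are bin centres.
make_disc <- function(levels, bin_count, spacing = c(1, 1, 1)) {
  mask <- !is.na(levels)
  w <- 20 / bin_count
  continuous <- array(NA_real_, dim(levels))
  continuous[mask] <- (levels[mask] - 0.5) * w
  structure(list(levels = levels, continuous = continuous, mask = mask,
                 bin_count = as.integer(bin_count), bounds = c(0, 20),
                 spacing = spacing, unit = "SUV"),
            class = "discretized_volume")
}

random_lesion <- function(dims = c(5, 5, 5), bin_count = 5, p_in = 0.7) {
  lev <- array(sample.int(bin_count, prod(dims), replace = TRUE), dims)
  mask <- array(stats::runif(prod(dims)) < p_in, dims)
  if (sum(mask) < 2) mask[1:2] <- TRUE
  lev[!mask] <- NA_integer_
  make_disc(lev, bin_count)
}

.offsets26 <- local({
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
})

.dirs13 <- local({
  keep <- logical(nrow(.offsets26))
  for (r in seq_len(nrow(.offsets26))) {
    nz <- .offsets26[r, ][.offsets26[r, ] != 0]
    keep[r] <- nz[1] > 0
  }
  .offsets26[keep, , drop = FALSE]
})

in_grid <- function(p, dims) all(p >= 1) && all(p <= dims)

oracle_glcm_matrix <- function(lev, nb) {
  dims <- dim(lev)
  cnt <- matrix(0, nb, nb)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    if (is.na(lev[x, y, z])) next
    for (o in seq_len(nrow(.offsets26))) {
      q <- c(x, y, z) + .offsets26[o, ]
      if (!in_grid(q, dims)) next
      lq <- lev[q[1], q[2], q[3]]
      if (is.na(lq)) next
      cnt[lev[x, y, z], lq] <- cnt[lev[x, y, z], lq] + 1
    }
  }
  if (sum(cnt) > 0) cnt / sum(cnt) else cnt
}

oracle_glcm_features <- function(p) {
  n <- nrow(p)
  hom <- en <- con <- dis <- ent <- num <- 0
  mu_i <- mu_j <- 0
  for (i in 1:n) for (j in 1:n) {
    mu_i <- mu_i + i * p[i, j]
    mu_j <- mu_j + j * p[i, j]
  }
  v_i <- v_j <- 0
  for (i in 1:n) for (j in 1:n) {
    pij <- p[i, j]
    hom <- hom + pij / (1 + abs(i - j))
    en <- en + pij^2
    con <- con + pij * (i - j)^2
    dis <- dis + pij * abs(i - j)
    if (pij > 0) ent <- ent - pij * log(pij)
    num <- num + pij * (i - mu_i) * (j - mu_j)
    v_i <- v_i + pij * (i - mu_i)^2
    v_j <- v_j + pij * (j - mu_j)^2
  }
  corr <- if (v_i <= 0 || v_j <= 0) 1 else num / sqrt(v_i * v_j)
  c(GLCM_Homogeneity = hom, GLCM_Energy = en, GLCM_Contrast = con,
    GLCM_Correlation = corr, GLCM_Entropy = ent,
    GLCM_Entropy_log2 = ent / log(2), GLCM_Dissimilarity = dis)
}

# runs along one direction, literal walk + manual run splitting
oracle_runs_dir <- function(lev, d) {
  dims <- dim(lev)
  out_lev <- integer(0); out_len <- integer(0)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    p <- c(x, y, z)
    if (is.na(lev[x, y, z])) next
    q <- p - d
    if (in_grid(q, dims) && !is.na(lev[q[1], q[2], q[3]])) next # not a line start
    seqv <- integer(0)
    r <- p
    while (in_grid(r, dims) && !is.na(lev[r[1], r[2], r[3]])) {
      seqv <- c(seqv, lev[r[1], r[2], r[3]])
      r <- r + d
    }
    start <- 1L
    for (i in seq_len(length(seqv) + 1L)) {
      if (i > length(seqv) || (i > start && seqv[i] != seqv[start])) {
        out_lev <- c(out_lev, seqv[start])
        out_len <- c(out_len, i - start)
        start <- i
      }
    }
  }
  list(lev = out_lev, len = out_len)
}

oracle_glrlm_matrix <- function(lev, nb, dirs = .dirs13) {
  rl <- integer(0); rn <- integer(0)
  for (k in seq_len(nrow(dirs))) {
    r <- oracle_runs_dir(lev, dirs[k, ])
    rl <- c(rl, r$lev); rn <- c(rn, r$len)
  }
  lmax <- max(rn)
  m <- matrix(0, nb, lmax)
  for (i in seq_along(rl)) m[rl[i], rn[i]] <- m[rl[i], rn[i]] + 1
  m
}

oracle_rl_features <- function(m, n_vox) {
  nr <- sum(m)
  sre <- lre <- lgre <- hgre <- srlge <- srhge <- lrlge <- lrhge <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    r <- m[i, j]
    if (r == 0) next
    sre <- sre + r / j^2; lre <- lre + r * j^2
    lgre <- lgre + r / i^2; hgre <- hgre + r * i^2
    srlge <- srlge + r / (i^2 * j^2); srhge <- srhge + r * i^2 / j^2
    lrlge <- lrlge + r * j^2 / i^2; lrhge <- lrhge + r * i^2 * j^2
  }
  glnu <- sum(apply(m, 1, sum)^2)
  rlnu <- sum(apply(m, 2, sum)^2)
  out <- c(sre, lre, lgre, hgre, srlge, srhge, lrlge, lrhge, glnu, rlnu) / nr
  c(out, nr / n_vox)
}

# zones by union-find over pairwise 26-adjacency of equal-level voxels
oracle_zones <- function(lev) {
  vox <- which(!is.na(lev))
  coords <- arrayInd(vox, dim(lev))
  n <- length(vox)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (lev[vox[i]] != lev[vox[j]]) next
      if (max(abs(coords[i, ] - coords[j, ])) <= 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- table(roots)
  data.frame(level = lev[vox[as.integer(names(sizes))]],
             size = as.integer(sizes))
}

oracle_glzlm_matrix <- function(lev, nb) {
  z <- oracle_zones(lev)
  m <- matrix(0, nb, max(z$size))
  for (i in seq_len(nrow(z))) m[z$level[i], z$size[i]] <- m[z$level[i], z$size[i]] + 1
  m
}

oracle_ngldm_features <- function(lev, cap = 1e6) {
  dims <- dim(lev)
  vox_lev <- integer(0); vox_diff <- numeric(0)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) for (z in seq_len(dims[3])) {
    if (is.na(lev[x, y, z])) next
    nb_sum <- 0; nb_n <- 0
    for (o in seq_len(nrow(.offsets26))) {
      q <- c(x, y, z) + .offsets26[o, ]
      if (!in_grid(q, dims)) next
      lq <- lev[q[1], q[2], q[3]]
      if (is.na(lq)) next
      nb_sum <- nb_sum + lq; nb_n <- nb_n + 1
    }
    if (nb_n == 0) next
    vox_lev <- c(vox_lev, lev[x, y, z])
    vox_diff <- c(vox_diff, abs(lev[x, y, z] - nb_sum / nb_n))
  }
  lv <- sort(unique(vox_lev))
  nvalid <- length(vox_lev)
  s <- p <- numeric(length(lv))
  for (k in seq_along(lv)) {
    s[k] <- sum(vox_diff[vox_lev == lv[k]])
    p[k] <- sum(vox_lev == lv[k]) / nvalid
  }
  coars <- if (sum(p * s) > 0) min(1 / sum(p * s), cap) else cap
  ng <- length(lv)
  contr <- 0; busy_den <- 0
  if (ng > 1) {
    for (a in seq_len(ng)) for (b in seq_len(ng)) {
      contr <- contr + p[a] * p[b] * (lv[a] - lv[b])^2
      busy_den <- busy_den + abs(lv[a] * p[a] - lv[b] * p[b])
    }
    contr <- contr / (ng * (ng - 1)) * sum(s) / nvalid
  }
  busy <- if (busy_den > 0) sum(p * s) / busy_den else 0
  c(NGLDM_Coarseness = coars, NGLDM_Contrast = contr, NGLDM_Busyness = busy)
}

oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (r in seq_len(m)) {
    cand <- Inf
    for (j in r:m) cand <- min(cand, p[o[j]] * m / j)
    q[o[r]] <- min(cand, 1)
  }
  q
}

# mutual information via entropies of the plug-in distribution
oracle_mi <- function(a, b) {
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log(p))
  }
  ent(a) + ent(b) - ent(paste(a, b))
}

oracle_ternarize <- function(x) {
  mu <- mean(x)
  sg <- sqrt(mean((x - mu)^2))
  if (sg == 0) return(rep(2L, length(x)))
  ifelse(x <= mu - sg, 1L, ifelse(x >= mu + sg, 3L, 2L))
}

oracle_mrmr <- function(xmat, y, k) {
  feats <- colnames(xmat)
  disc <- lapply(feats, function(f) oracle_ternarize(xmat[, f]))
  names(disc) <- feats
  sel <- character(0)
  while (length(sel) < k) {
    rem <- setdiff(feats, sel)
    best <- NULL; best_score <- -Inf
    for (f in rem) {
      rel <- oracle_mi(disc[[f]], y)
      red <- if (length(sel) == 0) 0
             else mean(vapply(sel, function(s) oracle_mi(disc[[f]], disc[[s]]),
                              numeric(1)))
      sc <- rel - red
      if (sc > best_score + 1e-12) {
        best <- f; best_score <- sc
      }
    }
    sel <- c(sel, best)
  }
  sel
}
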