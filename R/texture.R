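#' The 13 unique 3D directions at voxel distance 1
#'
#' Half of the 26-neighbourhood (one representative per +/- pair), used to
#' aggregate the co-occurrence and run-length matrices over all directions
#' into a single matrix before feature computation ("merged" aggregation).
#'
#' @return Integer matrix 13 x 3.
#' @keywords internal
texture_directions <- function() {
  off <- neighbour_offsets(26L)
  keep <- apply(off, 1L, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  off[keep, , drop = FALSE]
}

# out[p] = a[p + d]; NA where p + d falls outside the grid
shift_array <- function(a, d) {
  dims <- dim(a)
  out <- array(a[c(NA_integer_)], dim = dims) # NA of a's storage mode
  rng <- vector("list", 3L)
  for (k in 1:3) {
    lo <- max(1L, 1L - d[k])
    hi <- min(dims[k], dims[k] - d[k])
    if (hi < lo) return(out)
    rng[[k]] <- lo:hi
  }
  out[rng[[1]], rng[[2]], rng[[3]]] <-
    a[rng[[1]] + d[1], rng[[2]] + d[2], rng[[3]] + d[3]]
  out
}

#' Gray-level co-occurrence matrix
#'
#' Co-occurrences of in-VOI gray-level pairs at voxel distance 1, accumulated
#' over the 13 unique 3D directions, symmetrized and normalized to a
#' probability matrix.
#'
#' @param d A `discretized_volume` from [preprocess_volume()].
#' @param directions Integer matrix of direction offsets (default the 13
#'   unique 3D directions; a single row gives a one-direction matrix).
#' @return `bin_count` x `bin_count` probability matrix (sums to 1; all zero
#'   for an isolated single voxel).
#' @export
glcm_matrix <- function(d, directions = texture_directions()) {
  lev <- d$levels
  n <- d$bin_count
  counts <- matrix(0, n, n)
  dirs <- directions
  for (k in seq_len(nrow(dirs))) {
    dd <- dirs[k, ]
    sh <- shift_array(lev, dd)
    ok <- !is.na(lev) & !is.na(sh)
    if (!any(ok)) next
    i <- lev[ok]; j <- sh[ok]
    tab <- matrix(tabulate((i - 1L) * n + j, nbins = n * n), n, n, byrow = TRUE)
    counts <- counts + tab + t(tab)
  }
  s <- sum(counts)
  if (s > 0) counts / s else counts
}

glcm_features_from_matrix <- function(p) {
  n <- nrow(p)
  if (sum(p) == 0) {
    # isolated single voxel: no pairs exist; deterministic degenerate fill
    return(c(GLCM_Homogeneity = 1, GLCM_Energy = 1, GLCM_Contrast = 0,
             GLCM_Correlation = 1, GLCM_Entropy = 0, GLCM_Entropy_log2 = 0,
             GLCM_Dissimilarity = 0))
  }
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  pi_ <- rowSums(p)
  mu <- sum(seq_len(n) * pi_)
  sg <- sqrt(sum(pi_ * (seq_len(n) - mu)^2))
  pos <- p > 0
  ent <- -sum(p[pos] * log(p[pos]))
  corr <- if (sg == 0) 1 else sum(p * (i - mu) * (j - mu)) / (sg * sg)
  c(GLCM_Homogeneity = sum(p / (1 + abs(i - j))),
    GLCM_Energy = sum(p^2),
    GLCM_Contrast = sum(p * (i - j)^2),
    GLCM_Correlation = corr,
    GLCM_Entropy = ent,
    GLCM_Entropy_log2 = ent / log(2),
    GLCM_Dissimilarity = sum(p * abs(i - j)))
}

#' GLCM features
#'
#' Seven co-occurrence features (homogeneity, energy, contrast, correlation,
#' entropy in nats and bits, dissimilarity) from the direction-aggregated
#' symmetric GLCM. A single-gray-level lesion gives Energy 1, Entropy 0,
#' Contrast 0, Homogeneity 1, Dissimilarity 0 and Correlation defined as 1.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of length 7.
#' @export
glcm_features <- function(d) {
  glcm_features_from_matrix(glcm_matrix(d))
}

#' Gray-level run-length matrix
#'
#' Runs of consecutive equal gray levels along each of the 13 directions,
#' interrupted at the VOI boundary, accumulated into one counts matrix
#' (levels x run length).
#'
#' @inheritParams glcm_matrix
#' @return Counts matrix `bin_count` x (max run length).
#' @export
glrlm_matrix <- function(d, directions = texture_directions()) {
  lev <- d$levels
  dims <- dim(lev)
  dirs <- directions
  acc_lev <- vector("list", nrow(dirs))
  acc_len <- vector("list", nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    dd <- dirs[k, ]
    prev <- shift_array(lev, -dd)
    starts <- which(!is.na(lev) & is.na(prev))
    if (!length(starts)) next
    coords <- arrayInd(starts, dims)
    lv <- integer(0); ln <- integer(0)
    for (s in seq_along(starts)) {
      p <- coords[s, ]
      vals <- integer(0)
      repeat {
        vals <- c(vals, lev[p[1], p[2], p[3]])
        p <- p + dd
        if (any(p < 1L) || any(p > dims) || is.na(lev[p[1], p[2], p[3]])) break
      }
      r <- rle(vals)
      lv <- c(lv, r$values)
      ln <- c(ln, r$lengths)
    }
    acc_lev[[k]] <- lv
    acc_len[[k]] <- ln
  }
  lv <- unlist(acc_lev); ln <- unlist(acc_len)
  if (!length(lv)) return(matrix(0, d$bin_count, 1))
  lmax <- max(ln)
  m <- matrix(tabulate((lv - 1L) * lmax + ln, nbins = d$bin_count * lmax),
              d$bin_count, lmax, byrow = TRUE)
  m
}

rl_family_features <- function(m, n_vox, prefix, size_names) {
  nr <- sum(m)
  i <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  j <- matrix(rep(seq_len(ncol(m)), each = nrow(m)), nrow(m), ncol(m))
  f <- c(sum(m / j^2), sum(m * j^2), sum(m / i^2), sum(m * i^2),
         sum(m / (i^2 * j^2)), sum(m * i^2 / j^2), sum(m * j^2 / i^2),
         sum(m * i^2 * j^2), sum(rowSums(m)^2), sum(colSums(m)^2)) / nr
  out <- c(f, nr / n_vox)
  names(out) <- paste0(prefix, "_", size_names)
  out
}

#' GLRLM features
#'
#' Eleven run-length features (short/long run emphasis, low/high gray-level
#' emphasis and their four combinations, gray-level and run-length
#' non-uniformity, run percentage) from the direction-aggregated run-length
#' matrix. RP = runs / voxels.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of length 11.
#' @export
glrlm_features <- function(d) {
  m <- glrlm_matrix(d)
  rl_family_features(m, sum(!is.na(d$levels)), "GLRLM",
                     c("SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE",
                       "LRLGE", "LRHGE", "GLNU", "RLNU", "RP"))
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level inside the VOI; the
#' matrix counts zones by (level, zone size).
#'
#' @inheritParams glcm_matrix
#' @return Counts matrix `bin_count` x (max zone size).
#' @export
glzlm_matrix <- function(d) {
  lev <- d$levels
  present <- sort(unique(lev[!is.na(lev)]))
  zl <- integer(0); zs <- integer(0)
  for (l in present) {
    m <- !is.na(lev) & lev == l
    labs <- label_components(m, 26L)
    sizes <- tabulate(labs[labs > 0L])
    zl <- c(zl, rep(l, length(sizes)))
    zs <- c(zs, sizes)
  }
  if (!length(zl)) return(matrix(0, d$bin_count, 1))
  smax <- max(zs)
  matrix(tabulate((zl - 1L) * smax + zs, nbins = d$bin_count * smax),
         d$bin_count, smax, byrow = TRUE)
}

#' GLZLM features
#'
#' Eleven size-zone features, the run-length formula family with zone size in
#' place of run length; ZP = zones / voxels.
#'
#' @inheritParams glcm_matrix
#' @return Named numeric vector of length 11.
#' @export
glzlm_features <- function(d) {
  m <- glzlm_matrix(d)
  rl_family_features(m, sum(!is.na(d$levels)), "GLZLM",
                     c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE",
                       "LZLGE", "LZHGE", "GLNU", "ZLNU", "ZP"))
}

ngldm_stats <- function(d) {
  lev <- d$levels
  offs <- neighbour_offsets(26L)
  ssum <- array(0, dim(lev))
  cnt <- array(0L, dim(lev))
  for (k in seq_len(nrow(offs))) {
    sh <- shift_array(lev, offs[k, ])
    ok <- !is.na(sh)
    ssum[ok] <- ssum[ok] + sh[ok]
    cnt <- cnt + ok
  }
  valid <- !is.na(lev) & cnt > 0L
  li <- lev[valid]
  dv <- abs(li - ssum[valid] / cnt[valid])
  s_i <- tapply(dv, li, sum)
  n_i <- tapply(dv, li, length)
  levels_present <- as.integer(names(s_i))
  list(levels = levels_present, s = as.numeric(s_i), n = as.numeric(n_i),
       n_valid = sum(n_i))
}

#' NGLDM features
#'
#' Neighbourhood gray-tone difference statistics over the 26-neighbourhood
#' restricted to in-VOI neighbours: coarseness (capped at 1e6 for constant
#' lesions), contrast and busyness. A constant lesion gives contrast 0 and
#' busyness 0 with coarseness at the cap.
#'
#' @inheritParams glcm_matrix
#' @param coarseness_cap Upper cap for coarseness when the gray-tone
#'   difference sum vanishes.
#' @return Named numeric vector of length 3.
#' @export
ngldm_features <- function(d, coarseness_cap = 1e6) {
  st <- ngldm_stats(d)
  p_i <- st$n / st$n_valid
  denom_c <- sum(p_i * st$s)
  coarseness <- if (denom_c > 0) min(1 / denom_c, coarseness_cap) else coarseness_cap
  ng <- length(st$levels)
  contrast <- 0
  if (ng > 1) {
    ii <- outer(st$levels, st$levels, "-")^2
    pp <- outer(p_i, p_i)
    contrast <- sum(pp * ii) / (ng * (ng - 1)) * sum(st$s) / st$n_valid
  }
  busy_den <- 0
  if (ng > 1) {
    ip <- st$levels * p_i
    busy_den <- sum(abs(outer(ip, ip, "-")))
  }
  busyness <- if (busy_den > 0) sum(p_i * st$s) / busy_den else 0
  c(NGLDM_Coarseness = coarseness, NGLDM_Contrast = contrast,
    NGLDM_Busyness = busyness)
}
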