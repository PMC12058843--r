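# Shared fixtures, generated in code: small volumes, masks and
# independent brute-force oracles for the texture matrices.

rand_volume <- function(dim3 = c(8, 8, 8), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  volume_grid(array(rnorm(prod(dim3), -200, 150), dim3), spacing)
}

rand_mask <- function(dim3 = c(8, 8, 8), spacing = c(1, 1, 1), seed = 1,
                      p = 0.5) {
  set.seed(seed)
  m <- array(as.integer(runif(prod(dim3)) < p), dim3)
  if (sum(m) == 0) m[1] <- 1L
  mask_volume(m, spacing)
}

# discretised ROI with small Ng for oracle comparisons
rand_roi <- function(dim3 = c(6, 6, 6), ng = 4, seed = 1, p_mask = 0.7) {
  set.seed(seed)
  vals <- array(sample.int(ng, prod(dim3), replace = TRUE) * 10, dim3)
  m <- array(as.integer(runif(prod(dim3)) < p_mask), dim3)
  if (sum(m) == 0) m[1] <- 1L
  discretize(volume_grid(vals + 0.0, c(1, 1, 1)),
             mask_volume(m, c(1, 1, 1)), bin_width = 10)
}

sphere_mask <- function(diameter_mm, spacing = 0.5, margin_vox = 4) {
  n <- ceiling(diameter_mm / spacing) + 2 * margin_vox
  ax <- (seq_len(n) - 1) * spacing
  c0 <- (n - 1) * spacing / 2
  r2 <- outer(outer((ax - c0)^2, (ax - c0)^2, `+`), (ax - c0)^2, `+`)
  mask_volume(array(as.integer(r2 <= (diameter_mm / 2)^2), rep(n, 3)),
              rep(spacing, 3))
}

# the 13 displacement directions used by GLCM/GLRLM, duplicated here so
# the R oracles do not depend on the package's internals
DIRS13 <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

in_grid <- function(p, dm) all(p >= 1) && all(p <= dm)

# brute-force GLCM: enumerate every in-mask voxel pair per direction
oracle_glcm <- function(d) {
  dm <- dim(d$levels)
  out <- array(0L, c(d$ng, d$ng, 13))
  for (k in 1:13) {
    dd <- DIRS13[k, ]
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
      l1 <- d$levels[x, y, z]
      if (l1 == 0) next
      q <- c(x, y, z) + dd
      if (!in_grid(q, dm)) next
      l2 <- d$levels[q[1], q[2], q[3]]
      if (l2 == 0) next
      out[l1, l2, k] <- out[l1, l2, k] + 1L
      out[l2, l1, k] <- out[l2, l1, k] + 1L
    }
  }
  out
}

# brute-force GLRLM: walk every maximal run per direction
oracle_glrlm <- function(d) {
  dm <- dim(d$levels)
  runs <- list()
  for (k in 1:13) {
    dd <- DIRS13[k, ]
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
      l <- d$levels[x, y, z]
      if (l == 0) next
      prev <- c(x, y, z) - dd
      if (in_grid(prev, dm) && d$levels[prev[1], prev[2], prev[3]] == l)
        next
      len <- 1
      q <- c(x, y, z) + dd
      while (in_grid(q, dm) && d$levels[q[1], q[2], q[3]] == l) {
        len <- len + 1
        q <- q + dd
      }
      runs[[length(runs) + 1]] <- c(l, len, k)
    }
  }
  rr <- do.call(rbind, runs)
  out <- array(0L, c(d$ng, max(rr[, 2]), 13))
  for (i in seq_len(nrow(rr)))
    out[rr[i, 1], rr[i, 2], rr[i, 3]] <- out[rr[i, 1], rr[i, 2], rr[i, 3]] + 1L
  out
}

# brute-force GLSZM: repeated flood fill over 26-neighbourhoods
oracle_glszm <- function(d) {
  dm <- dim(d$levels)
  lev <- d$levels
  seen <- array(FALSE, dm)
  zones <- list()
  nbhd <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbhd <- nbhd[rowSums(abs(nbhd)) > 0, ]
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (seen[x, y, z] || lev[x, y, z] == 0) next
    l <- lev[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(nbhd))) {
        q <- p + nbhd[r, ]
        if (in_grid(q, dm) && !seen[q[1], q[2], q[3]] &&
            lev[q[1], q[2], q[3]] == l) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(l, size)
  }
  zz <- do.call(rbind, zones)
  out <- matrix(0L, d$ng, max(zz[, 2]))
  for (i in seq_len(nrow(zz)))
    out[zz[i, 1], zz[i, 2]] <- out[zz[i, 1], zz[i, 2]] + 1L
  out
}

# brute-force GLDM: count qualifying 26-neighbours per voxel
oracle_gldm <- function(d, alpha = 0L) {
  dm <- dim(d$levels)
  nbhd <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbhd <- nbhd[rowSums(abs(nbhd)) > 0, ]
  deps <- list()
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    l <- d$levels[x, y, z]
    if (l == 0) next
    dep <- 0
    for (r in seq_len(nrow(nbhd))) {
      q <- c(x, y, z) + nbhd[r, ]
      if (in_grid(q, dm) && d$levels[q[1], q[2], q[3]] > 0 &&
          abs(d$levels[q[1], q[2], q[3]] - l) <= alpha)
        dep <- dep + 1
    }
    deps[[length(deps) + 1]] <- c(l, dep + 1)
  }
  dd <- do.call(rbind, deps)
  out <- matrix(0L, d$ng, max(dd[, 2]))
  for (i in seq_len(nrow(dd)))
    out[dd[i, 1], dd[i, 2]] <- out[dd[i, 1], dd[i, 2]] + 1L
  out
}

# weighted average of pairwise CCCs; independent route to the OCCC
oracle_occc_pairwise <- function(mm) {
  J <- ncol(mm)
  n <- nrow(mm)
  f <- (n - 1) / n
  num <- 0
  den <- 0
  for (j in 1:(J - 1)) for (k in (j + 1):J) {
    x <- mm[, j]
    y <- mm[, k]
    w <- var(x) * f + var(y) * f + (mean(x) - mean(y))^2
    ccc <- if (w == 0) 1 else 2 * cov(x, y) * f / w
    num <- num + w * ccc
    den <- den + w
  }
  num / den
}
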