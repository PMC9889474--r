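# Shared fixtures, built in code.

# digital sphere/ellipsoid masks on a 1 mm grid
sphere_mask <- function(radius, margin = 12, spacing = c(1, 1, 1)) {
  half <- ceiling(radius + margin)
  d <- rep(2L * half + 1L, 3)
  DeltaRadiomics:::.ellipsoid_mask(d, spacing, rep(half, 3) * spacing,
                                   rep(radius, 3))
}

ellipsoid_mask <- function(radii, margin = 12) {
  half <- ceiling(radii + margin)
  d <- 2L * as.integer(half) + 1L
  DeltaRadiomics:::.ellipsoid_mask(d, c(1, 1, 1), half, radii)
}

# brute-force GLCM feature oracle for one offset (pair enumeration)
brute_glcm <- function(levels, nlev, off) {
  d <- dim(levels)
  P <- matrix(0, nlev, nlev)
  for (k in seq_len(d[3])) for (j in seq_len(d[2]))
    for (i in seq_len(d[1])) {
      a <- levels[i, j, k]
      if (a == 0) next
      i2 <- i + off[1]; j2 <- j + off[2]; k2 <- k + off[3]
      if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] ||
          k2 < 1 || k2 > d[3]) next
      b <- levels[i2, j2, k2]
      if (b == 0) next
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  if (sum(P) > 0) P <- P / sum(P)
  P
}

# brute-force run-length matrix oracle for one direction
brute_glrlm <- function(levels, nlev, dir) {
  d <- dim(levels)
  maxrun <- max(d)
  R <- matrix(0, nlev, maxrun)
  visited <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2]))
    for (i in seq_len(d[1])) {
      a <- levels[i, j, k]
      if (a == 0 || visited[i, j, k]) next
      # walk back to run start
      ip <- i - dir[1]; jp <- j - dir[2]; kp <- k - dir[3]
      if (ip >= 1 && ip <= d[1] && jp >= 1 && jp <= d[2] &&
          kp >= 1 && kp <= d[3] && levels[ip, jp, kp] == a) next
      len <- 0
      ci <- i; cj <- j; ck <- k
      while (ci >= 1 && ci <= d[1] && cj >= 1 && cj <= d[2] &&
             ck >= 1 && ck <= d[3] && levels[ci, cj, ck] == a) {
        visited[ci, cj, ck] <- TRUE
        len <- len + 1
        ci <- ci + dir[1]; cj <- cj + dir[2]; ck <- ck + dir[3]
      }
      R[a, len] <- R[a, len] + 1
    }
  R
}

# brute-force Harrell C oracle
brute_harrell <- function(risk, time, event) {
  conc <- 0; comp <- 0
  for (i in seq_along(time)) {
    if (!event[i]) next
    for (j in seq_along(time)) {
      if (time[i] < time[j]) {
        comp <- comp + 1
        conc <- conc + if (risk[i] > risk[j]) 1
                       else if (risk[i] == risk[j]) 0.5 else 0
      }
    }
  }
  conc / comp
}

# small survival dataset with planted linear hazard on given columns
planted_survival <- function(n, p, informative = integer(0), beta = 1.2,
                             seed = 1, baseline = 10, censor = 90) {
  withr::with_seed(seed, {
    X <- as.data.frame(matrix(rnorm(n * p), n))
    colnames(X) <- sprintf("f%02d", seq_len(p))
    risk <- if (length(informative))
      rowSums(beta * X[, informative, drop = FALSE]) else rep(0, n)
    tEvent <- rexp(n, rate = exp(risk) / baseline)
    tCens <- runif(n, 0, censor)
    list(X = X, time = pmin(tEvent, tCens),
         event = as.integer(tEvent <= tCens), risk = risk)
  })
}
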