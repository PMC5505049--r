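# Brute-force reference implementations, kept deliberately naive (explicit
# double loops, scalar accumulation) and independent of the package's
# vectorized code paths.

oracle_glcm <- function(L, G, orientation, distance = 1) {
  off <- switch(orientation,
                "0" = c(0, 1), "45" = c(-1, 1),
                "90" = c(-1, 0), "135" = c(-1, -1)) * distance
  counts <- matrix(0, G, G)
  for (r in seq_len(nrow(L))) {
    for (c in seq_len(ncol(L))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nrow(L) || c2 < 1 || c2 > ncol(L)) next
      if (is.na(L[r, c]) || is.na(L[r2, c2])) next
      counts[L[r, c], L[r2, c2]] <- counts[L[r, c], L[r2, c2]] + 1
      counts[L[r2, c2], L[r, c]] <- counts[L[r2, c2], L[r, c]] + 1
    }
  }
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

xlogx <- function(v) if (v > 0) v * log(v) else 0

oracle_features <- function(p) {
  G <- nrow(p)
  px <- numeric(G); py <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:G) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sigx2 <- 0; sigy2 <- 0
  for (i in 1:G) {
    sigx2 <- sigx2 + (i - mux)^2 * px[i]
    sigy2 <- sigy2 + (i - muy)^2 * py[i]
  }
  sigx <- sqrt(sigx2); sigy <- sqrt(sigy2)
  p_sum <- numeric(2 * G - 1)  # index k-1, k = 2..2G
  p_dif <- numeric(G)          # index k+1, k = 0..G-1
  for (i in 1:G) for (j in 1:G) {
    p_sum[i + j - 1] <- p_sum[i + j - 1] + p[i, j]
    p_dif[abs(i - j) + 1] <- p_dif[abs(i - j) + 1] + p[i, j]
  }
  autoc <- 0; contr <- 0; cprom <- 0; cshad <- 0; dissi <- 0
  energ <- 0; entro <- 0; homom <- 0; homop <- 0; sosvh <- 0
  indnc <- 0; indmc <- 0; cov_xy <- 0; hxy1 <- 0
  for (i in 1:G) for (j in 1:G) {
    v <- p[i, j]
    autoc <- autoc + i * j * v
    contr <- contr + (i - j)^2 * v
    cprom <- cprom + (i + j - mux - muy)^4 * v
    cshad <- cshad + (i + j - mux - muy)^3 * v
    dissi <- dissi + abs(i - j) * v
    energ <- energ + v^2
    entro <- entro - xlogx(v)
    homom <- homom + v / (1 + abs(i - j))
    homop <- homop + v / (1 + (i - j)^2)
    sosvh <- sosvh + (i - mux)^2 * v
    indnc <- indnc + v / (1 + abs(i - j) / G)
    indmc <- indmc + v / (1 + ((i - j) / G)^2)
    cov_xy <- cov_xy + (i - mux) * (j - muy) * v
    if (v > 0 && px[i] * py[j] > 0) hxy1 <- hxy1 - v * log(px[i] * py[j])
  }
  degenerate <- sigx == 0 || sigy == 0
  corrm <- if (degenerate) 0 else cov_xy / (sigx * sigy)
  corrp <- if (degenerate) 0 else (autoc - mux * muy) / (sigx * sigy)
  maxpr <- max(p)
  savgh <- 0; senth <- 0
  for (k in 2:(2 * G)) {
    savgh <- savgh + k * p_sum[k - 1]
    senth <- senth - xlogx(p_sum[k - 1])
  }
  svarh <- 0
  for (k in 2:(2 * G)) svarh <- svarh + (k - senth)^2 * p_sum[k - 1]
  dmean <- 0; dvar2 <- 0; denth <- 0
  for (k in 0:(G - 1)) dmean <- dmean + k * p_dif[k + 1]
  for (k in 0:(G - 1)) {
    dvar2 <- dvar2 + k^2 * p_dif[k + 1]
    denth <- denth - xlogx(p_dif[k + 1])
  }
  dvarh <- dvar2 - dmean^2
  hx <- 0; hy <- 0; hxy2 <- 0
  for (i in 1:G) { hx <- hx - xlogx(px[i]); hy <- hy - xlogx(py[i]) }
  for (i in 1:G) for (j in 1:G) hxy2 <- hxy2 - xlogx(px[i] * py[j])
  inf1h <- if (max(hx, hy) == 0) 0 else (entro - hxy1) / max(hx, hy)
  inf2h <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entro))))
  c(autoc = autoc, contr = contr, corrm = corrm, corrp = corrp,
    cprom = cprom, dissi = dissi, energ = energ, entro = entro,
    homom = homom, homop = homop, maxpr = maxpr, sosvh = sosvh,
    savgh = savgh, svarh = svarh, senth = senth, dvarh = dvarh,
    denth = denth, inf1h = inf1h, inf2h = inf2h, indnc = indnc,
    indmc = indmc, cshad = cshad)
}
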