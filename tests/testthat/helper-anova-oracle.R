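# independent brute-force oracle: balanced mixed-design sums of squares from
# explicit marginal means (equal group sizes keep all effects orthogonal)
oracle_mixed_anova <- function(Y, group) {
  A <- 2; M <- 4; N <- nrow(Y)
  gl <- sort(unique(group)); G <- length(gl); n <- N / G
  ad <- rep(1:A, each = M); mo <- rep(1:M, times = A)
  GM <- mean(Y)
  m_s <- rowMeans(Y)
  yg <- as.vector(tapply(m_s, group, mean))  # drop the 1-d array class
  ya <- vapply(1:A, function(a) mean(Y[, ad == a]), 1)
  ym <- vapply(1:M, function(m) mean(Y[, mo == m]), 1)
  ysa <- vapply(1:A, function(a) rowMeans(Y[, ad == a, drop = FALSE]), numeric(N))
  ysm <- vapply(1:M, function(m) rowMeans(Y[, mo == m, drop = FALSE]), numeric(N))
  yga <- outer(gl, 1:A, Vectorize(function(g, a) mean(Y[group == g, ad == a])))
  ygm <- outer(gl, 1:M, Vectorize(function(g, m) mean(Y[group == g, mo == m])))
  yam <- outer(1:A, 1:M, Vectorize(function(a, m) mean(Y[, ad == a & mo == m])))
  ygam <- array(0, c(G, A, M))
  for (gi in 1:G) for (a in 1:A) for (m in 1:M) {
    ygam[gi, a, m] <- mean(Y[group == gl[gi], ad == a & mo == m])
  }
  gi <- match(group, gl)

  SS_G <- A * M * n * sum((yg - GM)^2)
  SS_SG <- A * M * sum((m_s - yg[gi])^2)
  SS_A <- N * M * sum((ya - GM)^2)
  SS_GA <- M * n * sum((yga - outer(yg, rep(1, A)) -
                          outer(rep(1, G), ya) + GM)^2)
  SS_eA <- M * sum((ysa - m_s - yga[cbind(rep(gi, A), rep(1:A, each = N))] +
                      yg[gi])^2)
  SS_M <- N * A * sum((ym - GM)^2)
  SS_GM <- A * n * sum((ygm - outer(yg, rep(1, M)) -
                          outer(rep(1, G), ym) + GM)^2)
  SS_eM <- A * sum((ysm - m_s - ygm[cbind(rep(gi, M), rep(1:M, each = N))] +
                      yg[gi])^2)
  SS_AM <- N * sum((yam - outer(ya, rep(1, M)) -
                      outer(rep(1, A), ym) + GM)^2)
  SS_GAM <- 0; SS_eAM <- 0
  for (a in 1:A) for (m in 1:M) {
    cellgam <- ygam[, a, m] - yga[, a] - ygm[, m] - yam[a, m] +
      yg + ya[a] + ym[m] - GM
    SS_GAM <- SS_GAM + n * sum(cellgam^2)
    res <- Y[, ad == a & mo == m] - ysa[, a] - ysm[, m] + m_s -
      (ygam[gi, a, m] - yga[gi, a] - ygm[gi, m] + yg[gi])
    SS_eAM <- SS_eAM + sum(res^2)
  }
  Fs <- c(
    Group = (SS_G / (G - 1)) / (SS_SG / (N - G)),
    Adaptor = (SS_A / (A - 1)) / (SS_eA / ((A - 1) * (N - G))),
    `Adaptor:Group` = (SS_GA / ((A - 1) * (G - 1))) / (SS_eA / ((A - 1) * (N - G))),
    Morph = (SS_M / (M - 1)) / (SS_eM / ((M - 1) * (N - G))),
    `Morph:Group` = (SS_GM / ((M - 1) * (G - 1))) / (SS_eM / ((M - 1) * (N - G))),
    `Adaptor:Morph` = (SS_AM / ((A - 1) * (M - 1))) /
      (SS_eAM / ((A - 1) * (M - 1) * (N - G))),
    `Adaptor:Morph:Group` = (SS_GAM / ((A - 1) * (M - 1) * (G - 1))) /
      (SS_eAM / ((A - 1) * (M - 1) * (N - G))))
  list(F = Fs,
       SS = c(SS_G, SS_SG, SS_A, SS_GA, SS_eA, SS_M, SS_GM, SS_eM,
              SS_AM, SS_GAM, SS_eAM),
       SS_total = sum((Y - GM)^2))
}

prop_table_from_wide <- function(Y, group) {
  adaptors <- c("androgynous", "male"); morphs <- c(20, 40, 60, 80)
  rows <- list()
  for (s in seq_len(nrow(Y))) {
    j <- 0
    for (ad in adaptors) for (m in morphs) {
      j <- j + 1
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = sprintf("P%02d", s), group = group[s],
        adaptor = ad, morph_pct = m, p_male = Y[s, j], n_responded = 10L)
    }
  }
  structure(list(cells = do.call(rbind, rows), group_summary = NULL),
            class = "proportion_table")
}
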