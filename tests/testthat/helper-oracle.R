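# Independent, deliberately naive loop-based reference implementations of the
# 22 time-domain features. Kept free of any code path from the package so
# they can serve as an oracle.

oracle_quantile_lin <- function(x, p) {
  # linear-interpolation (type 7) quantile, hand-rolled
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

oracle_features <- function(x, fzc_t = 0.01, wa_t = 0.01, myop_t = 0.016,
                            card_t = 0.01, v = 2, eps = 1e-10) {
  n <- length(x)
  out <- numeric(0)

  iemg <- 0
  for (xi in x) iemg <- iemg + abs(xi)
  mav <- iemg / n

  mmav <- 0
  for (i in 1:n) {
    w <- if (i >= 0.25 * n && i <= 0.75 * n) 1 else 0.5
    mmav <- mmav + w * abs(x[i])
  }
  mmav <- mmav / n

  mmav2 <- 0
  for (i in 1:n) {
    w <- if (i >= 0.25 * n && i <= 0.75 * n) 1
         else if (i < 0.25 * n) 4 * i / n
         else 4 * (n - i) / n
    mmav2 <- mmav2 + w * abs(x[i])
  }
  mmav2 <- mmav2 / n

  emav <- 0
  for (i in 1:n) {
    p <- if (i >= 0.2 * n && i <= 0.8 * n) 0.75 else 0.5
    emav <- emav + abs(x[i])^p
  }
  emav <- emav / n

  ss <- 0
  for (xi in x) ss <- ss + xi^2
  rms <- sqrt(ss / n)

  sv <- 0
  for (xi in x) sv <- sv + abs(xi)^v
  vo <- (sv / n)^(1 / v)

  sl <- 0
  for (xi in x) sl <- sl + log(abs(xi) + eps)
  ld <- exp(sl / n)

  asm_acc <- 0 + 0i
  ass_acc <- 0 + 0i
  for (i in 1:n) {
    p <- if (i >= 0.2 * n && i <= 0.8 * n) 0.75 else 0.5
    asm_acc <- asm_acc + complex(real = x[i])^p
    ass_acc <- ass_acc + complex(real = x[i])^0.5
  }
  asm <- Mod(asm_acc)
  ass <- Mod(ass_acc)

  ewl <- 0
  for (i in 2:n) {
    p <- if (i >= 0.2 * n && i <= 0.8 * n) 0.75 else 0.5
    ewl <- ewl + abs(x[i] - x[i - 1])^p
  }
  damv <- 0
  dasdv <- 0
  for (i in 1:(n - 1)) {
    damv <- damv + abs(x[i + 1] - x[i])
    dasdv <- dasdv + (x[i + 1] - x[i])^2
  }
  ldamv <- log(damv / (n - 1) + eps)
  ldasdv <- log(sqrt(dasdv / (n - 1)) + eps)

  fzc <- 0; wa <- 0
  for (i in 1:(n - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= fzc_t) fzc <- fzc + 1
    if (abs(x[i + 1] - x[i]) >= wa_t) wa <- wa + 1
  }
  myop <- 0
  for (xi in x) if (abs(xi) >= myop_t) myop <- myop + 1
  myop <- myop / n
  s <- sort(x)
  card <- 0
  for (i in 1:(n - 1)) if (abs(s[i + 1] - s[i]) > card_t) card <- card + 1

  m <- 0
  for (xi in x) m <- m + xi
  m <- m / n
  ssq <- 0; sabs <- 0; s4 <- 0
  for (xi in x) {
    ssq <- ssq + (xi - m)^2
    sabs <- sabs + abs(xi - m)
    s4 <- s4 + (xi - m)^4
  }
  sdv <- sqrt(ssq / (n - 1))
  madm <- sabs / n
  iqr <- oracle_quantile_lin(x, 0.75) - oracle_quantile_lin(x, 0.25)
  m2 <- ssq / n
  kurt <- if (m2 == 0) NaN else (s4 / n) / m2^2
  cov <- sdv / (if (m == 0) eps else m)

  c(FZC = fzc, EWL = ewl, EMAV = emav, ASM = asm, ASS = ass, CARD = card,
    LDASDV = ldasdv, LDAMV = ldamv, MYOP = myop, VO = vo, MMAV = mmav,
    MMAV2 = mmav2, IEMG = iemg, RMS = rms, WA = wa, LD = ld, MAV = mav,
    MAD = madm, IQR = iqr, KURT = kurt, COV = cov, SD = sdv)
}
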