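# Independent brute-force oracles. These deliberately use naive nested
# loops and plainly transcribed formulas so they share no code path with
# the package implementations they check.

oracle_dirs13 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  as.matrix(g[g$dz > 0 | (g$dz == 0 & g$dy > 0) |
                (g$dz == 0 & g$dy == 0 & g$dx > 0), ])
})
oracle_dirs26 <- rbind(oracle_dirs13, -oracle_dirs13)

oracle_inside <- function(v, dims) {
  all(v >= 1) && all(v <= dims)
}

# ---- GLCM ------------------------------------------------------------------

oracle_glcm_features <- function(lev, ng) {
  dims <- dim(lev)
  acc <- NULL
  for (r in seq_len(nrow(oracle_dirs13))) {
    d <- as.integer(oracle_dirs13[r, ])
    P <- matrix(0, ng, ng)
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      if (is.na(lev[x, y, z])) next
      v2 <- c(x, y, z) + d
      if (!oracle_inside(v2, dims)) next
      j <- lev[v2[1], v2[2], v2[3]]
      if (is.na(j)) next
      i <- lev[x, y, z]
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
    if (sum(P) == 0) next
    acc <- rbind(acc, oracle_glcm_formulas(P / sum(P), ng))
  }
  colMeans(acc)
}

oracle_glcm_formulas <- function(p, ng) {
  lv <- seq_len(ng)
  px <- rowSums(p)
  mu <- 0; for (i in lv) mu <- mu + i * px[i]
  sig2 <- 0; for (i in lv) sig2 <- sig2 + (i - mu)^2 * px[i]
  pd <- rep(0, ng); ps <- rep(0, 2 * ng - 1)
  for (i in lv) for (j in lv) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + p[i, j]
  }
  kd <- 0:(ng - 1)
  da <- sum(kd * pd)
  H <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- H(p); hx <- H(px)
  hxy1 <- 0; hxy2 <- 0
  for (i in lv) for (j in lv) {
    if (px[i] * px[j] > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(px[i] * px[j])
      hxy2 <- hxy2 - px[i] * px[j] * log2(px[i] * px[j])
    }
  }
  s <- function(f) { t <- 0
    for (i in lv) for (j in lv) t <- t + f(i, j) * p[i, j]; t }
  c(Autocorrelation = s(function(i, j) i * j),
    ClusterProminence = s(function(i, j) (i + j - 2 * mu)^4),
    ClusterShade = s(function(i, j) (i + j - 2 * mu)^3),
    ClusterTendency = s(function(i, j) (i + j - 2 * mu)^2),
    Contrast = s(function(i, j) (i - j)^2),
    Correlation = if (sig2 > 0) (s(function(i, j) i * j) - mu^2) / sig2
                  else 1,
    DifferenceAverage = da,
    DifferenceEntropy = H(pd),
    DifferenceVariance = sum((kd - da)^2 * pd),
    Id = sum(pd / (1 + kd)),
    Idm = sum(pd / (1 + kd^2)),
    Idmn = sum(pd / (1 + kd^2 / ng^2)),
    Idn = sum(pd / (1 + kd / ng)),
    Imc1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    Imc2 = if (hxy2 > hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0,
    InverseVariance = if (ng > 1) sum(pd[-1] / kd[-1]^2) else 0,
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    SumEntropy = H(ps),
    SumSquares = sig2)
}

# ---- shared (level x size) family formulas ---------------------------------

oracle_family <- function(P, np) {
  ns <- sum(P)
  ng <- nrow(P); mx <- ncol(P)
  p <- P / ns
  small <- large <- lgl <- hgl <- slgl <- shgl <- llgl <- lhgl <- 0
  mui <- muj <- 0
  for (i in 1:ng) for (j in 1:mx) {
    small <- small + p[i, j] / j^2;  large <- large + p[i, j] * j^2
    lgl <- lgl + p[i, j] / i^2;      hgl <- hgl + p[i, j] * i^2
    slgl <- slgl + p[i, j] / (i^2 * j^2)
    shgl <- shgl + p[i, j] * i^2 / j^2
    llgl <- llgl + p[i, j] * j^2 / i^2
    lhgl <- lhgl + p[i, j] * i^2 * j^2
    mui <- mui + i * p[i, j];        muj <- muj + j * p[i, j]
  }
  glv <- szv <- 0
  for (i in 1:ng) for (j in 1:mx) {
    glv <- glv + (i - mui)^2 * p[i, j]
    szv <- szv + (j - muj)^2 * p[i, j]
  }
  q <- p[p > 0]
  c(small = small, large = large,
    gln = sum(rowSums(P)^2) / ns, glnn = sum(rowSums(P)^2) / ns^2,
    szn = sum(colSums(P)^2) / ns, sznn = sum(colSums(P)^2) / ns^2,
    pct = ns / np, glv = glv, szv = szv, ent = -sum(q * log2(q)),
    lgl = lgl, hgl = hgl, slgl = slgl, shgl = shgl, llgl = llgl,
    lhgl = lhgl)
}

# ---- GLRLM -----------------------------------------------------------------

oracle_glrlm_features <- function(lev, ng) {
  dims <- dim(lev)
  np <- sum(!is.na(lev))
  acc <- NULL
  for (r in seq_len(nrow(oracle_dirs13))) {
    d <- as.integer(oracle_dirs13[r, ])
    runs <- list()
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      if (is.na(lev[x, y, z])) next
      prev <- c(x, y, z) - d
      if (oracle_inside(prev, dims) &&
          !is.na(lev[prev[1], prev[2], prev[3]]) &&
          lev[prev[1], prev[2], prev[3]] == lev[x, y, z]) next
      len <- 1; cur <- c(x, y, z)
      repeat {
        nxt <- cur + d
        if (!oracle_inside(nxt, dims)) break
        if (is.na(lev[nxt[1], nxt[2], nxt[3]]) ||
            lev[nxt[1], nxt[2], nxt[3]] != lev[x, y, z]) break
        len <- len + 1; cur <- nxt
      }
      runs[[length(runs) + 1]] <- c(lev[x, y, z], len)
    }
    rl <- do.call(rbind, runs)
    P <- matrix(0, ng, max(rl[, 2]))
    for (i in seq_len(nrow(rl))) P[rl[i, 1], rl[i, 2]] <-
        P[rl[i, 1], rl[i, 2]] + 1
    f <- oracle_family(P, np)
    names(f) <- c("ShortRunEmphasis", "LongRunEmphasis",
      "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
      "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
      "RunPercentage", "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
    acc <- rbind(acc, f)
  }
  colMeans(acc)
}

# ---- GLSZM -----------------------------------------------------------------

oracle_glszm_features <- function(lev, ng) {
  dims <- dim(lev)
  np <- sum(!is.na(lev))
  seen <- array(FALSE, dims)
  zones <- list()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (is.na(lev[x, y, z]) || seen[x, y, z]) next
    level <- lev[x, y, z]
    stack <- list(c(x, y, z)); seen[x, y, z] <- TRUE; size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(oracle_dirs26))) {
        nb <- v + as.integer(oracle_dirs26[r, ])
        if (!oracle_inside(nb, dims)) next
        if (seen[nb[1], nb[2], nb[3]]) next
        if (is.na(lev[nb[1], nb[2], nb[3]]) ||
            lev[nb[1], nb[2], nb[3]] != level) next
        seen[nb[1], nb[2], nb[3]] <- TRUE
        stack[[length(stack) + 1]] <- nb
      }
    }
    zones[[length(zones) + 1]] <- c(level, size)
  }
  zn <- do.call(rbind, zones)
  P <- matrix(0, ng, max(zn[, 2]))
  for (i in seq_len(nrow(zn))) P[zn[i, 1], zn[i, 2]] <-
      P[zn[i, 1], zn[i, 2]] + 1
  f <- oracle_family(P, np)
  names(f) <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
    "ZonePercentage", "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
    "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
    "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
    "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  f
}

# ---- GLDM ------------------------------------------------------------------

oracle_gldm_features <- function(lev, ng) {
  dims <- dim(lev)
  np <- sum(!is.na(lev))
  recs <- list()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (is.na(lev[x, y, z])) next
    dep <- 1
    for (r in seq_len(nrow(oracle_dirs26))) {
      nb <- c(x, y, z) + as.integer(oracle_dirs26[r, ])
      if (!oracle_inside(nb, dims)) next
      if (!is.na(lev[nb[1], nb[2], nb[3]]) &&
          lev[nb[1], nb[2], nb[3]] == lev[x, y, z]) dep <- dep + 1
    }
    recs[[length(recs) + 1]] <- c(lev[x, y, z], dep)
  }
  rc <- do.call(rbind, recs)
  P <- matrix(0, ng, max(rc[, 2]))
  for (i in seq_len(nrow(rc))) P[rc[i, 1], rc[i, 2]] <-
      P[rc[i, 1], rc[i, 2]] + 1
  f <- oracle_family(P, np)
  names(f) <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "DependenceNonUniformity", "DependenceNonUniformityNormalized",
    "DependencePercentage", "GrayLevelVariance", "DependenceVariance",
    "DependenceEntropy", "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
    "SmallDependenceLowGrayLevelEmphasis",
    "SmallDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis",
    "LargeDependenceHighGrayLevelEmphasis")
  f[c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
      "GrayLevelNonUniformity", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "GrayLevelVariance",
      "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
      "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
      "SmallDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis",
      "LargeDependenceHighGrayLevelEmphasis")]
}

# ---- log-rank from hand-built risk tables ----------------------------------

oracle_logrank <- function(time, event, group) {
  # two groups; O - E with hypergeometric variance, summed over event times
  g <- as.integer(factor(group))
  tev <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in tev) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- (O1 - E1)^2 / V
  list(statistic = chi, p = pchisq(chi, 1, lower.tail = FALSE))
}

# ---- adjusted Rand index ---------------------------------------------------

adj_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  (sij - expected) / (mx - expected)
}

# random level array helper
random_levels <- function(dims, ng, seed) {
  set.seed(seed)
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  # carve a random mask but keep it non-empty
  drop <- runif(prod(dims)) < 0.2
  if (all(drop)) drop[1] <- FALSE
  lev[drop] <- NA_integer_
  lev[!is.na(lev)] <- as.integer(lev[!is.na(lev)])
  attr(lev, "Ng") <- ng
  lev
}
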