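# Independent brute-force oracles. Everything here is written as naive
# nested loops over voxels/levels, deliberately avoiding the vectorised
# code paths of the package, so that agreement is a genuine cross-check.

o_dirs <- function(mode) {
  if (mode == "2d") {
    list(c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(-1, 1, 0))
  } else {
    out <- list()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      o <- c(dx, dy, dz)
      if (all(o == 0)) next
      nz <- o[o != 0]
      if (nz[1] > 0) out[[length(out) + 1]] <- o
    }
    out
  }
}

o_neigh <- function(mode) {
  dirs <- o_dirs(mode)
  c(dirs, lapply(dirs, function(o) -o))
}

o_inb <- function(p, d) all(p >= 1) && all(p <= d)

# co-occurrence count matrix for one direction (symmetric, unnormalised)
o_glcm_matrix <- function(L, Ng, o) {
  d <- dim(L)
  M <- matrix(0, Ng, Ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- L[x, y, z]
    if (is.na(a)) next
    for (sgn in c(1, -1)) {
      q <- c(x, y, z) + sgn * o
      if (!o_inb(q, d)) next
      b <- L[q[1], q[2], q[3]]
      if (is.na(b)) next
      M[a, b] <- M[a, b] + 1
    }
  }
  M
}

o_glcm_features_one <- function(P) {
  Ng <- nrow(P)
  px <- numeric(Ng); py <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:Ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sigx <- 0; sigy <- 0
  for (i in 1:Ng) {
    sigx <- sigx + (i - mux)^2 * px[i]; sigy <- sigy + (i - muy)^2 * py[i]
  }
  sigx <- sqrt(sigx); sigy <- sqrt(sigy)
  psum <- numeric(2 * Ng); pdiff <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  lg <- function(v) if (v > 0) log2(v) else 0
  ac <- 0; cp <- 0; cs <- 0; ct <- 0; con <- 0; idf <- 0; idm <- 0
  idmn <- 0; idn <- 0; iv <- 0; je <- 0; jent <- 0; mp <- 0; ss <- 0
  hxy1 <- 0; hxy2 <- 0; cor_num <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    ac <- ac + i * j * p
    cp <- cp + (i + j - mux - muy)^4 * p
    cs <- cs + (i + j - mux - muy)^3 * p
    ct <- ct + (i + j - mux - muy)^2 * p
    con <- con + (i - j)^2 * p
    idf <- idf + p / (1 + abs(i - j))
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + ((i - j) / Ng)^2)
    idn <- idn + p / (1 + abs(i - j) / Ng)
    if (i != j) iv <- iv + p / (i - j)^2
    je <- je + p^2
    jent <- jent - p * lg(p)
    if (p > mp) mp <- p
    ss <- ss + (i - mux)^2 * p
    if (p > 0) hxy1 <- hxy1 - p * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
    cor_num <- cor_num + i * j * p
  }
  hx <- 0; hy <- 0
  for (i in 1:Ng) { hx <- hx - px[i] * lg(px[i]); hy <- hy - py[i] * lg(py[i]) }
  da <- 0
  for (k in 1:Ng) da <- da + (k - 1) * pdiff[k]
  de <- 0; dv <- 0
  for (k in 1:Ng) {
    de <- de - pdiff[k] * lg(pdiff[k])
    dv <- dv + ((k - 1) - da)^2 * pdiff[k]
  }
  sa <- 0; sent <- 0
  for (k in 2:(2 * Ng)) {
    sa <- sa + k * psum[k]
    sent <- sent - psum[k] * lg(psum[k])
  }
  corr <- if (sigx * sigy > 0) (cor_num - mux * muy) / (sigx * sigy) else 1
  imc1 <- if (max(hx, hy) > 0) (jent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - jent)), 0))
  occ <- which(px > 0)
  mcc <- if (length(occ) <= 1) 1 else {
    Q <- matrix(0, length(occ), length(occ))
    for (a in seq_along(occ)) for (b in seq_along(occ)) {
      s <- 0
      for (k in seq_along(occ))
        s <- s + P[occ[a], occ[k]] * P[occ[b], occ[k]] /
          (px[occ[a]] * py[occ[k]])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  }
  c(Autocorrelation = ac, JointAverage = mux, ClusterProminence = cp,
    ClusterShade = cs, ClusterTendency = ct, Contrast = con,
    Correlation = corr, DifferenceAverage = da, DifferenceEntropy = de,
    DifferenceVariance = dv, Id = idf, Idm = idm, Idmn = idmn, Idn = idn,
    Imc1 = imc1, Imc2 = imc2, InverseVariance = iv, JointEnergy = je,
    JointEntropy = jent, MCC = mcc, MaximumProbability = mp,
    SumAverage = sa, SumEntropy = sent, SumSquares = ss)
}

o_glcm_features <- function(L, Ng, mode) {
  acc <- NULL; nd <- 0
  for (o in o_dirs(mode)) {
    M <- o_glcm_matrix(L, Ng, o)
    if (sum(M) == 0) next
    f <- o_glcm_features_one(M / sum(M))
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  if (nd == 0) return(NULL)
  acc / nd
}

# run-length matrix by explicit line walking
o_glrlm_matrix <- function(L, Ng, o) {
  d <- dim(L)
  runs_g <- integer(0); runs_l <- integer(0)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    prev <- c(x, y, z) - o
    if (o_inb(prev, d)) next          # not a line start
    p <- c(x, y, z)
    cur <- NA; len <- 0
    while (o_inb(p, d)) {
      v <- L[p[1], p[2], p[3]]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) { runs_g <- c(runs_g, cur); runs_l <- c(runs_l, len) }
        cur <- v; len <- 1
      }
      p <- p + o
    }
    if (!is.na(cur)) { runs_g <- c(runs_g, cur); runs_l <- c(runs_l, len) }
  }
  if (length(runs_g) == 0) return(NULL)
  M <- matrix(0, Ng, max(runs_l))
  for (r in seq_along(runs_g))
    M[runs_g[r], runs_l[r]] <- M[runs_g[r], runs_l[r]] + 1
  M
}

o_rlm_features_one <- function(M, Np) {
  Ng <- nrow(M); Lm <- ncol(M)
  Nr <- sum(M)
  lg <- function(v) if (v > 0) log2(v) else 0
  gln <- 0; rln <- 0
  for (i in 1:Ng) gln <- gln + sum(M[i, ])^2
  for (l in 1:Lm) rln <- rln + sum(M[, l])^2
  mug <- 0; mul <- 0
  for (i in 1:Ng) for (l in 1:Lm) {
    mug <- mug + i * M[i, l] / Nr; mul <- mul + l * M[i, l] / Nr
  }
  glv <- 0; rv <- 0; rent <- 0; sre <- 0; lre <- 0; lgl <- 0; hgl <- 0
  srlgl <- 0; srhgl <- 0; lrlgl <- 0; lrhgl <- 0
  for (i in 1:Ng) for (l in 1:Lm) {
    p <- M[i, l] / Nr
    glv <- glv + (i - mug)^2 * p
    rv <- rv + (l - mul)^2 * p
    rent <- rent - p * lg(p)
    sre <- sre + M[i, l] / l^2
    lre <- lre + M[i, l] * l^2
    lgl <- lgl + M[i, l] / i^2
    hgl <- hgl + M[i, l] * i^2
    srlgl <- srlgl + M[i, l] / (i^2 * l^2)
    srhgl <- srhgl + M[i, l] * i^2 / l^2
    lrlgl <- lrlgl + M[i, l] * l^2 / i^2
    lrhgl <- lrhgl + M[i, l] * i^2 * l^2
  }
  c(GrayLevelNonUniformity = gln / Nr,
    GrayLevelNonUniformityNormalized = gln / Nr^2,
    GrayLevelVariance = glv,
    HighGrayLevelRunEmphasis = hgl / Nr,
    LongRunEmphasis = lre / Nr,
    LongRunHighGrayLevelEmphasis = lrhgl / Nr,
    LongRunLowGrayLevelEmphasis = lrlgl / Nr,
    LowGrayLevelRunEmphasis = lgl / Nr,
    RunEntropy = rent,
    RunLengthNonUniformity = rln / Nr,
    RunLengthNonUniformityNormalized = rln / Nr^2,
    RunPercentage = Nr / Np,
    RunVariance = rv,
    ShortRunEmphasis = sre / Nr,
    ShortRunHighGrayLevelEmphasis = srhgl / Nr,
    ShortRunLowGrayLevelEmphasis = srlgl / Nr)
}

o_glrlm_features <- function(L, Ng, mode) {
  Np <- sum(!is.na(L))
  acc <- NULL; nd <- 0
  for (o in o_dirs(mode)) {
    M <- o_glrlm_matrix(L, Ng, o)
    if (is.null(M)) next
    f <- o_rlm_features_one(M, Np)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  acc / nd
}

# zones by recursive flood fill
o_zones <- function(L, mode) {
  d <- dim(L)
  seen <- array(FALSE, d)
  neigh <- o_neigh(mode)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (seen[x, y, z] || is.na(L[x, y, z])) next
    g <- L[x, y, z]
    stack <- list(c(x, y, z)); seen[x, y, z] <- TRUE; size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (o in neigh) {
        q <- p + o
        if (!o_inb(q, d)) next
        if (seen[q[1], q[2], q[3]]) next
        v <- L[q[1], q[2], q[3]]
        if (is.na(v) || v != g) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  do.call(rbind, zones)
}

o_glszm_features <- function(L, Ng, mode) {
  zs <- o_zones(L, mode)
  Np <- sum(!is.na(L))
  Nz <- nrow(zs)
  g <- zs[, 1]; s <- zs[, 2]
  lg <- function(v) if (v > 0) log2(v) else 0
  gln <- 0
  for (i in 1:Ng) gln <- gln + sum(g == i)^2
  szn <- 0
  for (l in unique(s)) szn <- szn + sum(s == l)^2
  mug <- mean(g); mus <- mean(s)
  pz <- table(paste(g, s)) / Nz
  zent <- 0
  for (p in pz) zent <- zent - p * lg(p)
  c(GrayLevelNonUniformity = gln / Nz,
    GrayLevelNonUniformityNormalized = gln / Nz^2,
    GrayLevelVariance = mean((g - mug)^2),
    HighGrayLevelZoneEmphasis = mean(g^2),
    LargeAreaEmphasis = mean(s^2),
    LargeAreaHighGrayLevelEmphasis = mean(s^2 * g^2),
    LargeAreaLowGrayLevelEmphasis = mean(s^2 / g^2),
    LowGrayLevelZoneEmphasis = mean(1 / g^2),
    SizeZoneNonUniformity = szn / Nz,
    SizeZoneNonUniformityNormalized = szn / Nz^2,
    SmallAreaEmphasis = mean(1 / s^2),
    SmallAreaHighGrayLevelEmphasis = mean(g^2 / s^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (s^2 * g^2)),
    ZoneEntropy = zent,
    ZonePercentage = Nz / Np,
    ZoneVariance = mean((s - mus)^2))
}

o_gldm_features <- function(L, Ng, mode, alpha = 0) {
  d <- dim(L)
  neigh <- o_neigh(mode)
  gs <- integer(0); js <- integer(0)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    v <- L[x, y, z]
    if (is.na(v)) next
    dep <- 1
    for (o in neigh) {
      q <- c(x, y, z) + o
      if (!o_inb(q, d)) next
      w <- L[q[1], q[2], q[3]]
      if (!is.na(w) && abs(w - v) <= alpha) dep <- dep + 1
    }
    gs <- c(gs, v); js <- c(js, dep)
  }
  Nz <- length(gs)
  lg <- function(v) if (v > 0) log2(v) else 0
  M <- matrix(0, Ng, max(js))
  for (r in seq_along(gs)) M[gs[r], js[r]] <- M[gs[r], js[r]] + 1
  dn <- 0
  for (l in 1:ncol(M)) dn <- dn + sum(M[, l])^2
  gn <- 0
  for (i in 1:Ng) gn <- gn + sum(M[i, ])^2
  mug <- mean(gs); muj <- mean(js)
  dent <- 0
  for (i in 1:Ng) for (l in 1:ncol(M)) {
    p <- M[i, l] / Nz
    dent <- dent - p * lg(p)
  }
  c(DependenceEntropy = dent,
    DependenceNonUniformity = dn / Nz,
    DependenceNonUniformityNormalized = dn / Nz^2,
    DependenceVariance = mean((js - muj)^2),
    GrayLevelNonUniformity = gn / Nz,
    GrayLevelVariance = mean((gs - mug)^2),
    HighGrayLevelEmphasis = mean(gs^2),
    LargeDependenceEmphasis = mean(js^2),
    LargeDependenceHighGrayLevelEmphasis = mean(js^2 * gs^2),
    LargeDependenceLowGrayLevelEmphasis = mean(js^2 / gs^2),
    LowGrayLevelEmphasis = mean(1 / gs^2),
    SmallDependenceEmphasis = mean(1 / js^2),
    SmallDependenceHighGrayLevelEmphasis = mean(gs^2 / js^2),
    SmallDependenceLowGrayLevelEmphasis = mean(1 / (js^2 * gs^2)))
}

o_ngtdm_features <- function(L, Ng, mode) {
  d <- dim(L)
  neigh <- o_neigh(mode)
  n_i <- numeric(Ng); s_i <- numeric(Ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    v <- L[x, y, z]
    if (is.na(v)) next
    tot <- 0; cnt <- 0
    for (o in neigh) {
      q <- c(x, y, z) + o
      if (!o_inb(q, d)) next
      w <- L[q[1], q[2], q[3]]
      if (!is.na(w)) { tot <- tot + w; cnt <- cnt + 1 }
    }
    if (cnt == 0) next
    n_i[v] <- n_i[v] + 1
    s_i[v] <- s_i[v] + abs(v - tot / cnt)
  }
  Nvp <- sum(n_i)
  p_i <- n_i / Nvp
  pres <- which(n_i > 0)
  Ngp <- length(pres)
  coars_den <- sum(p_i * s_i)
  con <- 0; strg <- 0; den_bus <- 0; cmplx <- 0
  for (i in pres) for (j in pres) {
    con <- con + p_i[i] * p_i[j] * (i - j)^2
    strg <- strg + (p_i[i] + p_i[j]) * (i - j)^2
    den_bus <- den_bus + abs(i * p_i[i] - j * p_i[j])
    cmplx <- cmplx + abs(i - j) * (p_i[i] * s_i[i] + p_i[j] * s_i[j]) /
      (p_i[i] + p_i[j])
  }
  c(Coarseness = if (coars_den > 0) 1 / coars_den else 1e6,
    Contrast = if (Ngp > 1) con / (Ngp * (Ngp - 1)) * sum(s_i) / Nvp else 0,
    Busyness = if (den_bus > 0) coars_den / den_bus else 0,
    Complexity = cmplx / Nvp,
    Strength = if (sum(s_i) > 0) strg / sum(s_i) else 0)
}

# first-order oracle on raw values + level histogram
o_firstorder <- function(x, levels, Ng, voxvol) {
  n <- length(x)
  xs <- sort(x)
  pct <- function(q) {
    h <- (n - 1) * q + 1
    fl <- floor(h)
    xs[fl] + (h - fl) * (xs[min(fl + 1, n)] - xs[fl])
  }
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  p10 <- pct(0.1); p90 <- pct(0.9)
  sub <- x[x >= p10 & x <= p90]
  hcnt <- numeric(Ng)
  for (l in levels) hcnt[l] <- hcnt[l] + 1
  hp <- hcnt / n
  ent <- 0
  for (p in hp) if (p > 0) ent <- ent - p * log2(p)
  c(Energy = sum(x^2), TotalEnergy = voxvol * sum(x^2), Entropy = ent,
    Minimum = xs[1], `10Percentile` = p10, `90Percentile` = p90,
    Maximum = xs[n], Mean = mu, Median = pct(0.5),
    InterquartileRange = pct(0.75) - pct(0.25), Range = xs[n] - xs[1],
    MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    RobustMeanAbsoluteDeviation = sum(abs(sub - mean(sub))) / length(sub),
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2, Uniformity = sum(hp^2))
}

o_all_features <- function(roi, mode) {
  L <- roi@levels; Ng <- roi@Ng
  c(setNames(o_firstorder(roi@rawValues, L[!is.na(L)], Ng, roi@voxelVolume),
             paste0("firstorder_", names(o_firstorder(roi@rawValues,
                                                      L[!is.na(L)], Ng,
                                                      roi@voxelVolume)))),
    setNames(o_glcm_features(L, Ng, mode),
             paste0("glcm_", names(o_glcm_features(L, Ng, mode)))),
    setNames(o_glrlm_features(L, Ng, mode),
             paste0("glrlm_", names(o_glrlm_features(L, Ng, mode)))),
    setNames(o_glszm_features(L, Ng, mode),
             paste0("glszm_", names(o_glszm_features(L, Ng, mode)))),
    setNames(o_gldm_features(L, Ng, mode),
             paste0("gldm_", names(o_gldm_features(L, Ng, mode)))),
    setNames(o_ngtdm_features(L, Ng, mode),
             paste0("ngtdm_", names(o_ngtdm_features(L, Ng, mode)))))
}

# two-way ANOVA ICC oracle via stats::aov mean squares
o_icc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  list(icc31 = (msr - mse) / (msr + (k - 1) * mse),
       icc21 = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)))
}

# trapezoidal ROC AUC oracle
o_auc_trapezoid <- function(score, y) {
  th <- sort(unique(score), decreasing = TRUE)
  sens <- c(0); fpr <- c(0)
  for (t in th) {
    sens <- c(sens, mean(score[y == 1] >= t))
    fpr <- c(fpr, mean(score[y == 0] >= t))
  }
  sens <- c(sens, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
}

# stratified bootstrap oracle for the difference of paired AUCs
o_delong_bootstrap_p <- function(y, a, b, B = 1e5, seed = 99) {
  set.seed(seed)
  pos <- which(y == 1); neg <- which(y == 0)
  m <- length(pos); n <- length(neg)
  Ma <- outer(a[pos], a[neg], function(u, v) (u > v) + 0.5 * (u == v))
  Mb <- outer(b[pos], b[neg], function(u, v) (u > v) + 0.5 * (u == v))
  D <- Ma - Mb
  obs <- mean(D)
  diffs <- numeric(B)
  for (r in seq_len(B)) {
    cp <- tabulate(sample.int(m, m, replace = TRUE), m)
    cn <- tabulate(sample.int(n, n, replace = TRUE), n)
    diffs[r] <- as.numeric(cp %*% D %*% cn) / (m * n)
  }
  ## normal-theory p from the bootstrap SE of the AUC difference
  2 * stats::pnorm(-abs(obs) / stats::sd(diffs))
}
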