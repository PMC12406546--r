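# Independent brute-force oracle for the 20 GLCM texture features.
# Every quantity is computed with literal element-wise loops over the
# co-occurrence matrix, sharing no code with the package implementation.
# Logarithms base 2; 0 * log 0 := 0; same degenerate conventions
# (correlation := 1 when a marginal is constant, IMCI := 0 when
# max(HX, HY) = 0, IMCII radicand clamped at 0).

oracle_texture_features <- function(p) {
  ng <- nrow(p)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mu_x <- 0; mu_y <- 0
  for (i in 1:ng) { mu_x <- mu_x + i * px[i]; mu_y <- mu_y + i * py[i] }
  var_x <- 0; var_y <- 0
  for (i in 1:ng) {
    var_x <- var_x + (i - mu_x)^2 * px[i]
    var_y <- var_y + (i - mu_y)^2 * py[i]
  }
  sig_x <- sqrt(var_x); sig_y <- sqrt(var_y)

  psum <- numeric(2 * ng)          # indexed by k = 2..2*ng
  pdiff <- numeric(ng)             # indexed by k + 1, k = 0..ng-1
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }

  hx <- 0
  for (i in 1:ng) if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
  hy <- 0
  for (j in 1:ng) if (py[j] > 0) hy <- hy - py[j] * log2(py[j])
  hxy <- 0; hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    if (p[i, j] > 0) {
      hxy <- hxy - p[i, j] * log2(p[i, j])
      hxy1 <- hxy1 - p[i, j] * log2(px[i] * py[j])
    }
    if (px[i] * py[j] > 0)
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
  }

  asm <- 0; contrast <- 0; autoc <- 0; sos <- 0; idm <- 0
  maxp <- 0; cprom <- 0; cshade <- 0; inn <- 0; idn <- 0; dissim <- 0
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    asm <- asm + v^2
    contrast <- contrast + (i - j)^2 * v
    autoc <- autoc + i * j * v
    sos <- sos + (i - mu_x)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    if (v > maxp) maxp <- v
    cprom <- cprom + (i + j - mu_x - mu_y)^4 * v
    cshade <- cshade + (i + j - mu_x - mu_y)^3 * v
    inn <- inn + v / (1 + abs(i - j) / ng)
    idn <- idn + v / (1 + (i - j)^2 / ng^2)
    dissim <- dissim + abs(i - j) * v
  }

  sum_avg <- 0
  for (k in 2:(2 * ng)) sum_avg <- sum_avg + k * psum[k]
  sum_var <- 0; sum_ent <- 0
  for (k in 2:(2 * ng)) {
    sum_var <- sum_var + (k - sum_avg)^2 * psum[k]
    if (psum[k] > 0) sum_ent <- sum_ent - psum[k] * log2(psum[k])
  }
  mu_d <- 0
  for (k in 0:(ng - 1)) mu_d <- mu_d + k * pdiff[k + 1]
  dvar <- 0; dent <- 0
  for (k in 0:(ng - 1)) {
    dvar <- dvar + (k - mu_d)^2 * pdiff[k + 1]
    if (pdiff[k + 1] > 0) dent <- dent - pdiff[k + 1] * log2(pdiff[k + 1])
  }

  corr <- if (sig_x * sig_y == 0) 1 else (autoc - mu_x * mu_y) / (sig_x * sig_y)
  hmax <- max(hx, hy)
  imci <- if (hmax == 0) 0 else (hxy - hxy1) / hmax
  imcii <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  c(angular_second_moment = asm, contrast = contrast, correlation = corr,
    sum_of_squares_variance = sos, inverse_difference_moment = idm,
    sum_average = sum_avg, sum_variance = sum_var, sum_entropy = sum_ent,
    entropy = hxy, difference_variance = dvar, difference_entropy = dent,
    IMCI = imci, IMCII = imcii, autocorrelation = autoc,
    maximum_probability = maxp, cluster_prominence = cprom,
    cluster_shade = cshade, INN = inn, IDN = idn, dissimilarity = dissim)
}

# Random symmetric normalized GLCM with ng levels.
random_glcm_matrix <- function(ng) {
  counts <- matrix(rpois(ng * ng, 3) + matrix(runif(ng * ng) < 0.2, ng, ng),
                   ng, ng)
  counts <- counts + t(counts)
  if (sum(counts) == 0) counts[1, 1] <- 2
  counts / sum(counts)
}

# Wrap a probability matrix in the package's glcm class so
# texture_features() can consume it directly.
as_glcm <- function(p) {
  structure(list(p = p, n_pairs = 1L, distance = 1L,
                 directions = glcm_directions(), symmetric = TRUE,
                 n_levels = nrow(p)),
            class = "glcm")
}
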