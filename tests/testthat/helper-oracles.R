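# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# unit vectors on the p-sphere from a grid of spherical angles
# rows of `theta` (G x (p-1) angles) -> p x G matrix of unit vectors
angles_to_units <- function(theta) {
  theta <- as.matrix(theta)
  g <- nrow(theta); p <- ncol(theta) + 1
  A <- matrix(0, p, g)
  s <- rep(1, g)
  for (i in seq_len(p - 1)) {
    A[i, ] <- s * cos(theta[, i])
    s <- s * sin(theta[, i])
  }
  A[p, ] <- s
  A
}

# mean over responses of cor^2(Y_j, X a) for every column a of A
grid_objective <- function(X, Y, A) {
  Fm <- X %*% A
  num <- colSums(crossprod(Y, Fm)^2)
  den <- (nrow(X) - 1) * colSums(scale(Fm, scale = FALSE)^2) * ncol(Y)
  ifelse(den > 0, num / den, 0)
}

# brute-force maximizer of the factor-1 explained response variation over
# unit predictor-weight vectors: coarse spherical grid plus successive local
# refinement passes around the best point so far
rrr_grid_max <- function(X, Y, steps = 24, refine = 15, passes = 3,
                         n_basins = 20) {
  p <- ncol(X)
  stopifnot(p <= 4)
  coarse <- seq(0, pi, length.out = steps)
  ang <- as.matrix(expand.grid(rep(list(coarse), ncol(X) - 1)))
  obj <- grid_objective(X, Y, angles_to_units(ang))
  best_obj <- max(obj)
  # refine around several coarse candidates: the global basin need not hold
  # the single best coarse point
  for (idx in order(obj, decreasing = TRUE)[seq_len(n_basins)]) {
    best <- ang[idx, ]
    step <- pi / (steps - 1)
    for (pass in seq_len(passes)) {
      fine <- lapply(best, function(b) seq(b - step, b + step,
                                           length.out = refine))
      ang2 <- as.matrix(expand.grid(fine))
      obj2 <- grid_objective(X, Y, angles_to_units(ang2))
      if (max(obj2) > best_obj) best_obj <- max(obj2)
      best <- ang2[which.max(obj2), ]
      step <- 2 * step / (refine - 1)
    }
  }
  best_obj
}

# a small standardized random instance for RRR tests
random_rrr_instance <- function(seed, n = 200, p = 4, m = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  W <- matrix(rnorm(p * m), p, m)
  Y <- X %*% W + matrix(rnorm(n * m, sd = 2), n, m)
  X <- standardize_columns(X)$z
  Y <- standardize_columns(Y)$z
  colnames(X) <- paste0("X", seq_len(p))
  colnames(Y) <- c("zn", "pufa")[seq_len(m)]
  list(X = X, Y = Y)
}

# tiny participant table for filter tests, all fields plausible by default
toy_participants <- function(n = 5) {
  gi <- as.data.frame(matrix(100, n, 68))
  names(gi) <- c(paste0(tolower(food_group_ids()), "_day1"),
                 paste0(tolower(food_group_ids()), "_day2"))
  base <- data.frame(
    id = seq_len(n), sex = "female", age = 40, race = "Non-Hispanic White",
    education = "Some college/AA", pir = 2.5, vigorous_work = 0,
    vigorous_rec = 0, lipid_lowering = 0, supplement_use = 0, pregnant = 0,
    weight_kg = 70, height_cm = 165, stringsAsFactors = FALSE
  )
  out <- cbind(base, gi)
  # energy close to pTEE so everyone is a plausible reporter
  ptee <- predict_tee(out$age, out$weight_kg, out$height_cm, 1)
  out$energy_day1_kcal <- ptee / 0.004184
  out$energy_day2_kcal <- ptee / 0.004184
  out$energy_kcal <- ptee / 0.004184
  out$zn_mg <- 10
  out$pufa_g <- 17
  out$serum_la <- 3500
  out$serum_dgla <- 150
  out$la_dgla_ratio <- out$serum_la / out$serum_dgla
  out$serum_zn <- 90
  out
}
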