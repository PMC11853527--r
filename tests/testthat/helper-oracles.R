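# Independent oracles used to cross-check package computations.

# Horn quaternion superposition: minimum RMSD of mobile P onto reference Q.
# Independent of the SVD-based Kabsch path used by the package.
horn_rmsd <- function(P, Q) {
  cP <- colMeans(P); cQ <- colMeans(Q)
  p <- sweep(P, 2, cP); q <- sweep(Q, 2, cQ)
  S <- crossprod(p, q)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[1,3]+S[3,1],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[1,3]+S[3,1],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  ev <- eigen(K, symmetric = TRUE)
  quat <- ev$vectors[, 1]
  w <- quat[1]; x <- quat[2]; y <- quat[3]; z <- quat[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  moved <- p %*% t(R)
  sqrt(mean(rowSums((moved - q)^2)))
}

# Random proper rotation matrix.
random_rotation <- function() {
  A <- matrix(rnorm(9), 3, 3)
  qr_dec <- qr(A)
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Brute-force double loop for windowed per-residue mutation counts.
brute_window_counts <- function(positions, L, window) {
  half <- (window - 1) / 2
  vapply(seq_len(L), function(i) {
    sum(vapply(positions, function(p) abs(p - i) <= half &&
                 p >= 1 && p <= L, logical(1)))
  }, numeric(1))
}

# Brute-force grid search for the GHK permeability-ratio bound.
grid_perm_bound <- function(epsilon, pH_o = 7.5, pH_i = 6.5, c_TMA_mM = 100,
                            T_K = 294, n_grid = 200001) {
  E_H <- hv1kit::nernst_potential(pH_o, pH_i, T_K)
  lr <- seq(-6, 18, length.out = n_grid)
  dev <- abs(hv1kit::ghk_vrev(10^lr, pH_o, pH_i, c_TMA_mM, T_K) - E_H)
  10^lr[which(dev <= epsilon)[1]]
}

# Deterministic mutation table with 197 records (134 missense, 51 silent,
# 12 stop) touching exactly 125 distinct residues of a 273-residue protein.
count_matched_table <- function() {
  pos_unique <- 1:125                  # 125 distinct affected residues
  pos_extra <- rep(1:72, 1)            # 72 recurrent records at known sites
  pos <- c(pos_unique, pos_extra)      # 197 records in total
  cls <- c(rep("missense", 134), rep("silent", 51), rep("stop", 12))
  ref <- rep("R", 197)
  alt <- ifelse(cls == "missense", "W", ifelse(cls == "silent", "=", "*"))
  data.frame(position = pos, ref_aa = ref, alt_aa = alt,
             source_db = "SYNTHDB-1", tissue = "synthetic",
             sample_id = sprintf("S%03d", 1:197))
}

# Toy two-residue ensemble with a prescribed donor-acceptor distance per
# frame (Arg NH1 against Asp OD1).
pair_distance_ensemble <- function(distances) {
  atoms <- data.frame(
    resno = c(1, 1, 1, 1, 2, 2),
    resid = c("ARG", "ARG", "ARG", "ARG", "ASP", "ASP"),
    elety = c("CA", "NE", "NH1", "NH2", "CA", "OD1"))
  coords <- array(0, c(6, 3, length(distances)))
  for (f in seq_along(distances)) {
    xyz <- matrix(0, 6, 3)
    xyz[1, ] <- c(-2, 0, 0)          # Arg CA
    xyz[2, ] <- c(-1, 0.5, 0)        # NE
    xyz[3, ] <- c(0, 0, 0)           # NH1 (donor used for the distance)
    xyz[4, ] <- c(-0.5, -1, 0)       # NH2
    xyz[5, ] <- c(distances[f] + 1.5, 0, 0)  # Asp CA
    xyz[6, ] <- c(distances[f], 0, 0)        # OD1
    coords[, , f] <- xyz
  }
  hv1kit::structure_ensemble(atoms, coords, label = "pair-toy")
}
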