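#' Residue geometric centers from an atom table
#'
#' @param atoms `cmhs_atoms` data.frame (see [read_pdb()]) with columns
#'   residue_index, atom_name, x, y, z
#' @return n_residues x 3 matrix of unweighted atom-coordinate means, rows
#'   ordered by residue index
#' @export
residue_centroids <- function(atoms) {
  stopifnot(all(c("residue_index", "x", "y", "z") %in% names(atoms)))
  idx <- sort(unique(atoms$residue_index))
  out <- matrix(NA_real_, length(idx), 3L)
  for (i in seq_along(idx)) {
    sub <- atoms[atoms$residue_index == idx[i], , drop = FALSE]
    if (!nrow(sub)) cmhs_stop(sprintf("residue %d has no atoms", idx[i]),
                              "cmhs_structure_error")
    out[i, ] <- c(mean(sub$x), mean(sub$y), mean(sub$z))
  }
  rownames(out) <- idx
  out
}

#' Calpha coordinates from an atom table, centroid fallback
#'
#' Uses the CA atom of each residue when present; residues without a CA
#' fall back to the all-atom centroid.
#' @inheritParams residue_centroids
#' @return n_residues x 3 coordinate matrix
#' @export
residue_coords <- function(atoms) {
  ca <- atoms[atoms$atom_name == "CA", , drop = FALSE]
  idx <- sort(unique(atoms$residue_index))
  if (nrow(ca) && setequal(ca$residue_index, idx)) {
    ca <- ca[!duplicated(ca$residue_index), , drop = FALSE]
    ca <- ca[order(ca$residue_index), , drop = FALSE]
    out <- as.matrix(ca[, c("x", "y", "z")])
    rownames(out) <- ca$residue_index
    return(out)
  }
  residue_centroids(atoms)
}

#' Residue contact adjacency at a distance threshold
#'
#' `A[i, j] = 1` iff `i != j` and the Euclidean distance is strictly below
#' the threshold (8 Angstrom by convention). Symmetric, zero diagonal.
#' @param coords n x 3 coordinate matrix
#' @param threshold contact cutoff in Angstrom
#' @return n x n 0/1 matrix
#' @export
contact_adjacency <- function(coords, threshold = 8) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  a <- (d < threshold) * 1
  diag(a) <- 0
  unname(a)
}

#' Kirchhoff (graph Laplacian) matrix of a contact graph
#'
#' Off-diagonal entries are -1 for contacting pairs and 0 otherwise; the
#' diagonal holds node degrees, so every row sums to zero.
#' @param A symmetric 0/1 adjacency with zero diagonal
#' @return Kirchhoff matrix, positive semidefinite
#' @export
gnm_kirchhoff <- function(A) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 0)) {
    cmhs_stop("adjacency must be symmetric", "cmhs_validation_error")
  }
  if (any(diag(A) != 0)) {
    cmhs_stop("adjacency must have a zero diagonal", "cmhs_validation_error")
  }
  gamma <- -(A > 0) * 1
  diag(gamma) <- -rowSums(gamma)
  unname(gamma)
}

#' Count connected components of a 0/1 adjacency
#' @keywords internal
.graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, which(A[v, ] > 0 & comp == 0L))
    }
  }
  comp
}

#' Gaussian Network Model B-factors
#'
#' The predicted relative B-factor of residue i is the i-th diagonal entry
#' of the Moore-Penrose pseudoinverse of the Kirchhoff matrix, times a
#' scale collecting the physical constants (k_B T / gamma; relative values
#' suffice, so the default scale is 1). The Kirchhoff matrix of a connected
#' graph has exactly one zero mode, which the pseudoinverse excludes; on a
#' disconnected graph each component contributes a zero mode and a warning
#' is emitted.
#'
#' @param gamma Kirchhoff matrix from [gnm_kirchhoff()]
#' @param scale multiplicative constant (k_B T / gamma)
#' @return numeric vector of non-negative B-factors
#' @export
gnm_bfactor <- function(gamma, scale = 1) {
  gamma <- as.matrix(gamma)
  n <- nrow(gamma)
  if (n < 2L) cmhs_stop("GNM undefined for fewer than 2 residues",
                        "cmhs_structure_error")
  A <- (gamma < 0) * 1
  ncomp <- max(.graph_components(A))
  if (ncomp > 1L) {
    warning(sprintf("contact graph has %d components; %d zero modes dropped",
                    ncomp, ncomp))
  }
  ginv <- .pinv(gamma)
  b <- scale * diag(ginv)
  pmax(b, 0)
}

# SVD pseudoinverse with a spectral tolerance (the implementation route;
# the test suite checks it against an eigendecomposition oracle).
.pinv <- function(m, tol = NULL) {
  s <- svd(m)
  if (is.null(tol)) tol <- max(dim(m)) * max(s$d) * .Machine$double.eps * 100
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Map B-factors to noise standard deviations (sigmoid form)
#'
#' `g(B) = sigma_min + (sigma_max - sigma_min) / (1 + exp(-k (B - B_m)))`:
#' flexible (high-B) residues get noisier cross edges, saturating at
#' `sigma_max`; rigid residues floor at `sigma_min`.
#'
#' @param B numeric vector of B-factors
#' @param sigma_min,sigma_max bounds of the output range
#' @param k sigmoid steepness (> 0)
#' @param B_m midpoint; default the median of `B` (per-structure centering)
#' @return vector of standard deviations in (sigma_min, sigma_max)
#' @export
sigma_from_bfactor <- function(B, sigma_min = 0.01, sigma_max = 0.5,
                               k = 1, B_m = NULL) {
  if (sigma_min >= sigma_max) {
    cmhs_stop("sigma_min must be < sigma_max", "cmhs_config_error")
  }
  if (k <= 0) cmhs_stop("k must be > 0", "cmhs_config_error")
  if (is.null(B_m)) B_m <- stats::median(B)
  sigma_min + (sigma_max - sigma_min) / (1 + exp(-k * (B - B_m)))
}

#' Noise specification for cross-edge adjacency perturbation
#'
#' The mean map is `mu = gain * (A - rowmean(A))`, a trainable scalar gain
#' (zero-initialized, so training starts from the clean graph); the
#' per-MHC-node standard deviation comes from [sigma_from_bfactor()].
#'
#' @param gain scalar gain of the mean map
#' @param sigma_min,sigma_max,k,B_m passed to [sigma_from_bfactor()]
#' @return object of class `cmhs_adj_noise`
#' @export
adj_noise_spec <- function(gain = 0, sigma_min = 0.01, sigma_max = 0.5,
                           k = 1, B_m = NULL) {
  if (sigma_min >= sigma_max) {
    cmhs_stop("sigma_min must be < sigma_max", "cmhs_config_error")
  }
  structure(list(gain = gain, sigma_min = sigma_min, sigma_max = sigma_max,
                 k = k, B_m = B_m), class = "cmhs_adj_noise")
}

#' B-factor-guided Gaussian noise on a cross adjacency
#'
#' In training mode returns `A + eps` with `eps[i, j] ~ N(mu[i, j],
#' sigma[i]^2)`, `mu = gain * (A - rowmean(A))` and `sigma[i]` derived from
#' the GNM B-factor of MHC node i. At inference the clean adjacency is
#' returned unchanged.
#'
#' @param A_cross real matrix, MHC x peptide orientation
#' @param gnm_b B-factors aligned with the rows of `A_cross`
#' @param spec [adj_noise_spec()]
#' @param seed integer seed (draws are reproducible)
#' @param training logical; noise only in training mode
#' @return matrix of the same dimension
#' @export
adjacency_noise <- function(A_cross, gnm_b, spec = adj_noise_spec(),
                            seed = 1L, training = TRUE) {
  A_cross <- as.matrix(A_cross)
  if (length(gnm_b) != nrow(A_cross)) {
    cmhs_stop("B-factor length must match rows of the cross adjacency",
              "cmhs_dimension_error")
  }
  if (!training) return(A_cross)
  sigma <- sigma_from_bfactor(gnm_b, spec$sigma_min, spec$sigma_max,
                              spec$k, spec$B_m)
  mu <- spec$gain * (A_cross - rowMeans(A_cross))
  eps <- with_seed(seed, matrix(stats::rnorm(length(A_cross)),
                                nrow(A_cross)) * sigma + mu)
  A_cross + eps
}

#' Build the heterogeneous MHC-peptide graph
#'
#' MHC nodes carry the structural contact adjacency `A_mm`
#' ([contact_adjacency()] on Calpha coordinates); every peptide position is
#' initially linked to every pseudo-sequence (binding-site) MHC residue as
#' a dense candidate cross-edge set, which cross-attention later re-weights
#' and top-k extraction prunes. Node types tau and edge types phi follow
#' from the partition (MHC-MHC within `A_mm`; MHC-Peptide / Peptide-MHC on
#' the cross edges).
#'
#' @param mhc_coords n x 3 Calpha coordinate matrix
#' @param pseudo_positions 1-based MHC residue indices of the binding site
#' @param peptide_length number of peptide nodes (8-12)
#' @param contact_threshold Angstrom cutoff for `A_mm`
#' @return object of class `cmhs_hetero_graph` with fields V_M, V_P, A_mm,
#'   E_mp, E_pm, pseudo_positions, tau, coords
#' @export
build_hetero_graph <- function(mhc_coords, pseudo_positions, peptide_length,
                               contact_threshold = 8) {
  mhc_coords <- as.matrix(mhc_coords)
  n <- nrow(mhc_coords)
  pseudo_positions <- sort(unique(as.integer(pseudo_positions)))
  if (any(pseudo_positions < 1L) || any(pseudo_positions > n)) {
    cmhs_stop(sprintf("pseudo position out of range 1..%d", n),
              "cmhs_validation_error")
  }
  stopifnot(peptide_length >= 1L)
  A_mm <- contact_adjacency(mhc_coords, contact_threshold)
  E_mp <- matrix(0, n, peptide_length)
  E_mp[pseudo_positions, ] <- 1
  g <- list(
    V_M = seq_len(n),
    V_P = seq_len(peptide_length),
    A_mm = A_mm,
    E_mp = E_mp,
    E_pm = t(E_mp),
    pseudo_positions = pseudo_positions,
    tau = c(rep("MHC", n), rep("Peptide", peptide_length)),
    coords = mhc_coords
  )
  class(g) <- "cmhs_hetero_graph"
  g
}

#' Edge type of a heterogeneous-graph edge
#' @param graph `cmhs_hetero_graph`
#' @param from,to node labels: "m<i>" for MHC node i, "p<j>" for peptide j
#' @return "MHC-MHC", "MHC-Peptide" or "Peptide-MHC"
#' @export
edge_type <- function(graph, from, to) {
  kind <- function(lab) if (startsWith(lab, "m")) "MHC" else "Peptide"
  a <- kind(from); b <- kind(to)
  if (a == "MHC" && b == "MHC") "MHC-MHC"
  else if (a == "MHC" && b == "Peptide") "MHC-Peptide"
  else if (a == "Peptide" && b == "MHC") "Peptide-MHC"
  else cmhs_stop("peptide-peptide edges are not part of the graph schema",
                 "cmhs_validation_error")
}

#' Serialize a heterogeneous graph to the documented JSON layout
#'
#' Layout: `nodes` (id, type), `edges` split by type with 1-based endpoint
#' indices; MHC-MHC edges are the upper triangle of `A_mm`.
#' @param graph `cmhs_hetero_graph`
#' @param path output file; when NULL the JSON string is returned
#' @export
hetero_graph_to_json <- function(graph, path = NULL) {
  n <- length(graph$V_M); p <- length(graph$V_P)
  mm <- which(upper.tri(graph$A_mm) & graph$A_mm > 0, arr.ind = TRUE)
  mp <- which(graph$E_mp > 0, arr.ind = TRUE)
  obj <- list(
    nodes = data.frame(
      id = c(paste0("m", seq_len(n)), paste0("p", seq_len(p))),
      type = graph$tau),
    edges = list(
      `MHC-MHC` = data.frame(from = mm[, 1L], to = mm[, 2L]),
      `MHC-Peptide` = data.frame(from = mp[, 1L], to = mp[, 2L]),
      `Peptide-MHC` = data.frame(from = mp[, 2L], to = mp[, 1L])),
    pseudo_positions = graph$pseudo_positions
  )
  json <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
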