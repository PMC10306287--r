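#' Probability density of a hydrogen-bond distance series
#'
#' Gaussian kernel density estimate (Silverman bandwidth by default) for a
#' frame-wise donor--acceptor distance, e.g. the Asp--substrate Od2--O2
#' distance whose intact state peaks near 2.8 A.
#'
#' @param series numeric vector of distances (A), or a data frame with a
#'   `distance_A` column. At least 50 frames are required.
#' @param bandwidth kernel bandwidth in A, or `NULL` for Silverman's rule.
#' @return a `density_estimate`: tibble `grid_A`, `density` with attributes
#'   `bandwidth` and `n`; the trapezoidal integral is 1 to within 1e-3.
#' @export
distance_density <- function(series, bandwidth = NULL) {
  v <- .as_distance_vector(series)
  if (length(v) < 50) stop("insufficient data: need >= 50 frames", call. = FALSE)
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(v) else bandwidth
  stopifnot(bw > 0)
  d <- stats::density(v, bw = bw, n = 2048, cut = 4)
  out <- tibble::tibble(grid_A = d$x, density = d$y)
  attr(out, "bandwidth") <- bw
  attr(out, "n") <- length(v)
  class(out) <- c("density_estimate", class(out))
  out
}

.as_distance_vector <- function(series) {
  v <- if (is.data.frame(series)) {
    if (!"distance_A" %in% names(series)) {
      stop("missing column(s): distance_A", call. = FALSE)
    }
    series$distance_A
  } else {
    series
  }
  if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
    stop("distances must be finite and positive", call. = FALSE)
  }
  v
}

#' Mode of a density estimate
#'
#' @param dens a `density_estimate`.
#' @param below optional upper distance bound (A) restricting the search.
#' @return the grid location of the density maximum, A (`NA` if the
#'   restricted grid is empty).
#' @export
density_mode <- function(dens, below = Inf) {
  keep <- dens$grid_A < below
  if (!any(keep)) return(NA_real_)
  dens$grid_A[keep][which.max(dens$density[keep])]
}

#' Two-state occupancy of a distance series
#'
#' Frames below the threshold count as the active (hydrogen-bond intact)
#' state; the default 3.4 A cutoff lies midway between the ~2.8 A intact
#' peak and typical broken-state distances.
#'
#' @inheritParams distance_density
#' @param threshold_A active/inactive distance cutoff, A.
#' @return one-row tibble `fraction_active`, `fraction_inactive`,
#'   `active_peak_A` (density mode below threshold; `NA` if unoccupied),
#'   `threshold_A`, `n_frames`.
#' @export
classify_states <- function(series, threshold_A = 3.4, bandwidth = NULL) {
  stopifnot(threshold_A > 0)
  v <- .as_distance_vector(series)
  frac <- mean(v < threshold_A)
  peak <- if (frac > 0 && length(v) >= 50) {
    density_mode(distance_density(v, bandwidth), below = threshold_A)
  } else if (frac > 0) {
    stats::median(v[v < threshold_A])
  } else {
    NA_real_
  }
  tibble::tibble(
    fraction_active = frac,
    fraction_inactive = 1 - frac,
    active_peak_A = peak,
    threshold_A = threshold_A,
    n_frames = length(v)
  )
}

# ---- coordinate trajectories ------------------------------------------------

.BACKBONE <- c("N", "CA", "C", "O")

.check_trajectory <- function(traj) {
  need <- c("frame", "atom", "residue", "x", "y", "z")
  miss <- setdiff(need, names(traj))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  counts <- table(traj$frame)
  if (length(unique(counts)) != 1) {
    stop("atom count differs between frames", call. = FALSE)
  }
  invisible(traj)
}

# long tibble -> list(coords = array[atoms, 3, frames], atoms = lookup tibble)
.traj_array <- function(traj) {
  .check_trajectory(traj)
  traj <- dplyr::arrange(traj, .data$frame, .data$atom)
  frames <- unique(traj$frame)
  nf <- length(frames)
  na <- nrow(traj) / nf
  coords <- array(NA_real_, c(na, 3, nf))
  m <- as.matrix(traj[, c("x", "y", "z")])
  for (i in seq_len(nf)) {
    coords[, , i] <- m[((i - 1) * na + 1):(i * na), ]
  }
  atoms <- traj[seq_len(na), setdiff(names(traj), c("frame", "x", "y", "z"))]
  list(coords = coords, atoms = atoms, frames = frames)
}

.traj_tibble <- function(arr, superposed = FALSE) {
  nf <- dim(arr$coords)[3]
  na <- dim(arr$coords)[1]
  xyz <- do.call(rbind, lapply(seq_len(nf), function(i) arr$coords[, , i]))
  out <- tibble::as_tibble(arr$atoms[rep(seq_len(na), nf), ])
  out$frame <- rep(arr$frames, each = na)
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out <- dplyr::relocate(out, "frame")
  attr(out, "superposed") <- superposed
  out
}

# Kabsch rotation R minimising |P R - Q| for centred row-vector coordinates
.kabsch <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

.selection_index <- function(atoms, selection) {
  idx <- if (identical(selection, "backbone")) {
    if ("name" %in% names(atoms)) which(atoms$name %in% .BACKBONE)
    else if ("backbone" %in% names(atoms)) which(as.logical(atoms$backbone))
    else seq_len(nrow(atoms))
  } else if (identical(selection, "all")) {
    seq_len(nrow(atoms))
  } else {
    which(atoms$atom %in% selection)
  }
  if (length(idx) == 0) stop("empty atom selection", call. = FALSE)
  idx
}

#' Rigid-body superposition of a trajectory
#'
#' Least-squares (Kabsch) superposition of every frame onto an iterated mean
#' structure: frames are first aligned on the selection to frame 1, then to
#' the mean of the aligned frames (two passes). Removes global rotation and
#' translation so that residual displacements reflect internal mobility.
#'
#' @param traj long-form trajectory tibble with columns
#'   `frame, atom, residue, x, y, z` and optionally `name` (atom names,
#'   used for the backbone selection).
#' @param selection `"backbone"` (default), `"all"`, or a vector of atom ids.
#' @return the trajectory with transformed coordinates and attribute
#'   `superposed = TRUE`.
#' @export
superpose <- function(traj, selection = "backbone") {
  arr <- .traj_array(traj)
  idx <- .selection_index(arr$atoms, selection)
  if (length(idx) < 3) stop("selection must contain >= 3 atoms", call. = FALSE)
  nf <- dim(arr$coords)[3]

  ref <- arr$coords[idx, , 1]
  sv <- svd(scale(ref, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    stop("degenerate (collinear) selection: superposition is ill-defined",
         call. = FALSE)
  }

  align_all <- function(coords, ref_sel) {
    mu_ref <- colMeans(ref_sel)
    for (i in seq_len(nf)) {
      sel <- coords[idx, , i]
      mu <- colMeans(sel)
      R <- .kabsch(sweep(sel, 2, mu), sweep(ref_sel, 2, mu_ref))
      coords[, , i] <- sweep(sweep(coords[, , i], 2, mu) %*% R, 2, mu_ref, "+")
    }
    coords
  }

  arr$coords <- align_all(arr$coords, ref)
  for (pass in 1:2) {
    mean_ref <- apply(arr$coords[idx, , , drop = FALSE], c(1, 2), mean)
    arr$coords <- align_all(arr$coords, mean_ref)
  }
  .traj_tibble(arr, superposed = TRUE)
}

#' Per-residue backbone RMSF
#'
#' Root-mean-square fluctuation about the time-mean position, pooled over
#' frames and the backbone atoms (N, CA, C, O) of each residue:
#' \eqn{\mathrm{RMSF}_r = \sqrt{\langle |x - \bar{x}|^2 \rangle}}.
#' The input should be superposed first ([superpose()]); a warning is issued
#' otherwise.
#'
#' @inheritParams superpose
#' @return tibble `residue`, `rmsf_A`.
#' @export
rmsf <- function(traj) {
  .check_trajectory(traj)
  if (!isTRUE(attr(traj, "superposed"))) {
    warning("trajectory is not flagged as superposed; RMSF will include ",
            "global rigid-body motion", call. = FALSE)
  }
  if (length(unique(traj$frame)) < 2) {
    stop("insufficient data: need >= 2 frames", call. = FALSE)
  }
  bb <- if ("name" %in% names(traj)) {
    dplyr::filter(traj, .data$name %in% .BACKBONE)
  } else {
    traj
  }
  bb |>
    dplyr::group_by(.data$residue, .data$atom) |>
    dplyr::mutate(dx = .data$x - mean(.data$x),
                  dy = .data$y - mean(.data$y),
                  dz = .data$z - mean(.data$z)) |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(
      rmsf_A = sqrt(mean(.data$dx^2 + .data$dy^2 + .data$dz^2)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$residue)
}

#' Ratio of mean RMSF between two profiles over a residue window
#'
#' Quantifies relative loop mobility, e.g. the ~2-fold damping of a surface
#' loop in a stabilised variant relative to the wild type.
#'
#' @param a,b RMSF profiles from [rmsf()] (tibbles `residue`, `rmsf_A`).
#' @param residues optional vector of residue indices defining the window;
#'   default: all residues present in both profiles.
#' @return `mean(a)/mean(b)` over the shared window.
#' @export
rmsf_ratio <- function(a, b, residues = NULL) {
  shared <- intersect(a$residue, b$residue)
  if (!is.null(residues)) shared <- intersect(shared, residues)
  if (length(shared) == 0) stop("empty residue overlap", call. = FALSE)
  mean(a$rmsf_A[a$residue %in% shared]) / mean(b$rmsf_A[b$residue %in% shared])
}
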