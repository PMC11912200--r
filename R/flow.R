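# Flow models C and H. Both map supercell Cartesian coordinates r to the
# 3(N-1) marginal variables x through fixed, data-fitted representation
# layers (virtual-site removal, oxygen-COM removal, PCA whitening, and for
# model H internal coordinates + hemisphere quaternions + hyperspherical
# angles, all shift-scaled into [-1, 1]), then through trainable spline
# coupling layers x -> z. The base distribution over z is flat: uniform
# [-1, 1] per dimension for model C; for model H the three angle dimensions
# of each molecule are distributed as a uniform rotation on the q0 >= 0
# hemisphere of S^3 expressed in hyperspherical coordinates. Every layer
# contributes an exact log-volume, so ln q(r) is normalized by construction.

# ---- encoder: r <-> x ------------------------------------------------------

fit_flow_encoder <- function(frames, kind = c("H", "C"), clip = 1e-8,
                             margin = 0.01) {
  kind <- match.arg(kind)
  if (any(frames$roles == "M")) frames <- drop_virtual_site(frames)
  frames <- remove_oxygen_com(frames)
  n_mol <- frames$topology$n_mol
  if (n_mol < 2) abort("flow models need at least 2 molecules")
  o_idx <- atom_indices(frames, "O")
  O <- flatten_coords(frames$coords[, o_idx, , drop = FALSE])
  wt <- fit_whitening(O)
  wh <- whiten(wt, O)

  d_wo <- 3L * (n_mol - 1L)
  if (kind == "C") {
    h_idx <- which(frames$roles %in% c("H1", "H2"))
    H <- flatten_coords(frames$coords[, h_idx, , drop = FALSE])
    X <- cbind(wh$y, H)
    tags <- c(rep("wO", d_wo), rep("hcart", 6L * n_mol))
    periodic <- rep(FALSE, ncol(X))
    ss <- fit_shift_scale(X, margin = margin)
    enc <- list(kind = kind, topology = frames$topology, whitening = wt,
                shift_scale = ss, offsets = NULL, clip = clip,
                n_mol = n_mol, D = ncol(X), tags = tags, periodic = periodic,
                h_idx = h_idx,
                wo_cols = seq_len(d_wo),
                h_cols = d_wo + seq_len(6L * n_mol))
  } else {
    internal <- molecules_to_internal(frames)
    q <- internal$quat
    for (m in seq_len(n_mol)) q[, m, ] <- fix_hemisphere(matrix(q[, m, ], ncol = 4))
    offsets <- align_reference_rotations(q)
    q <- apply_rotation_offsets(q, offsets)
    ang <- array(0, c(dim(q)[1], n_mol, 3))
    for (m in seq_len(n_mol)) {
      hs <- quat_to_hyperspherical(matrix(q[, m, ], ncol = 4), clip = clip)
      ang[, m, ] <- hs$angles
    }
    int_cols <- matrix(d_wo + seq_len(3L * n_mol), nrow = n_mol, byrow = TRUE)
    ang_cols <- matrix(d_wo + 3L * n_mol + seq_len(3L * n_mol),
                       nrow = n_mol, byrow = TRUE)
    X <- matrix(0, dim(q)[1], d_wo + 6L * n_mol)
    X[, seq_len(d_wo)] <- wh$y
    for (m in seq_len(n_mol)) {
      X[, int_cols[m, ]] <- cbind(internal$d1[, m], internal$d2[, m],
                                  internal$theta[, m])
      X[, ang_cols[m, ]] <- ang[, m, ]
    }
    tags <- c(rep("wO", d_wo),
              rep(c("bond", "bond", "angle"), n_mol),
              rep(c("t0", "t1", "t2"), n_mol))
    periodic <- tags == "t2"
    fixed <- matrix(NA_real_, ncol(X), 2)
    fixed[tags == "t0", ] <- matrix(c(0, pi / 2), sum(tags == "t0"), 2, byrow = TRUE)
    fixed[tags == "t1", ] <- matrix(c(0, pi), sum(tags == "t1"), 2, byrow = TRUE)
    fixed[tags == "t2", ] <- matrix(c(0, 2 * pi), sum(tags == "t2"), 2, byrow = TRUE)
    ss <- fit_shift_scale(X, margin = margin, fixed_ranges = fixed)
    enc <- list(kind = kind, topology = frames$topology, whitening = wt,
                shift_scale = ss, offsets = offsets, clip = clip,
                n_mol = n_mol, D = ncol(X), tags = tags, periodic = periodic,
                wo_cols = seq_len(d_wo), int_cols = int_cols,
                ang_cols = ang_cols)
  }
  class(enc) <- "flow_encoder"
  enc
}

# r -> x with the accumulated log-volume of that direction
encode_frames <- function(enc, frames) {
  if (any(frames$roles == "M")) frames <- drop_virtual_site(frames)
  frames <- remove_oxygen_com(frames)
  nf <- n_frames(frames)
  n_mol <- enc$n_mol
  o_idx <- atom_indices(frames, "O")
  O <- flatten_coords(frames$coords[, o_idx, , drop = FALSE])
  wh <- whiten(enc$whitening, O)
  lv <- rep(wh$log_volume, nf)
  X <- matrix(0, nf, enc$D)
  X[, enc$wo_cols] <- wh$y
  n_singular <- 0L
  if (enc$kind == "C") {
    h_idx <- which(frames$roles %in% c("H1", "H2"))
    X[, enc$h_cols] <- flatten_coords(frames$coords[, h_idx, , drop = FALSE])
  } else {
    internal <- molecules_to_internal(frames)
    lv <- lv + internal$log_volume
    q <- internal$quat
    for (m in seq_len(n_mol)) q[, m, ] <- fix_hemisphere(matrix(q[, m, ], ncol = 4))
    q <- apply_rotation_offsets(q, enc$offsets)
    for (m in seq_len(n_mol)) {
      hs <- quat_to_hyperspherical(matrix(q[, m, ], ncol = 4), clip = enc$clip)
      X[, enc$ang_cols[m, ]] <- hs$angles
      lv <- lv + hs$log_volume
      n_singular <- n_singular + sum(hs$singular)
      X[, enc$int_cols[m, ]] <- cbind(internal$d1[, m], internal$d2[, m],
                                      internal$theta[, m])
    }
  }
  sf <- shift_scale_forward(enc$shift_scale, X)
  list(x = sf$y, log_volume = lv + sf$log_volume, n_singular = n_singular)
}

# x -> r with the accumulated log-volume of that direction
decode_x <- function(enc, x, temperature = NULL) {
  nf <- nrow(x)
  n_mol <- enc$n_mol
  si <- shift_scale_inverse(enc$shift_scale, x)
  X <- si$x
  lv <- rep(si$log_volume, nf)
  uw <- unwhiten(enc$whitening, X[, enc$wo_cols, drop = FALSE])
  lv <- lv + uw$log_volume
  r_O <- unflatten_coords(uw$x)
  if (enc$kind == "C") {
    coords <- array(0, c(nf, 3L * n_mol, 3))
    H <- unflatten_coords(X[, enc$h_cols, drop = FALSE])
    for (m in seq_len(n_mol)) {
      at <- (m - 1L) * 3L
      coords[, at + 1L, ] <- r_O[, m, ]
      coords[, at + 2L, ] <- H[, 2L * m - 1L, ]
      coords[, at + 3L, ] <- H[, 2L * m, ]
    }
    frames <- supercell_frames(coords, enc$topology, temperature = temperature)
    return(list(frames = frames, log_volume = lv))
  }
  quat <- array(0, c(nf, n_mol, 4))
  d1 <- d2 <- theta <- matrix(0, nf, n_mol)
  for (m in seq_len(n_mol)) {
    hq <- hyperspherical_to_quat(X[, enc$ang_cols[m, ], drop = FALSE],
                                 clip = enc$clip)
    quat[, m, ] <- hq$q
    lv <- lv + hq$log_volume
    d1[, m] <- X[, enc$int_cols[m, 1]]
    d2[, m] <- X[, enc$int_cols[m, 2]]
    theta[, m] <- X[, enc$int_cols[m, 3]]
  }
  quat <- apply_rotation_offsets(quat, enc$offsets, inverse = TRUE, refix = FALSE)
  im <- internal_to_molecules(
    list(d1 = d1, d2 = d2, theta = theta, quat = quat, r_O = r_O),
    enc$topology, temperature = temperature
  )
  list(frames = im$frames, log_volume = lv + im$log_volume)
}

# ---- model -----------------------------------------------------------------

#' Build a flow model (kind C or H)
#'
#' Fits the fixed representation layers (whitening, shift-scale, and for
#' model H the per-molecule reference rotations) on the supplied data set —
#' the *entire* data set, training plus validation, is used for these
#' layers — and stacks `n_layers` identity-initialised rational-quadratic
#' spline coupling layers on top. Model C represents hydrogens by their
#' Cartesian coordinates; model H by bond lengths, bond angle and
#' hemisphere-quaternion hyperspherical angles, with the `theta2` dimensions
#' flagged periodic and handled by circular splines.
#'
#' @param frames a [supercell_frames()] ensemble used to fit the fixed layers.
#' @param kind `"H"` (hemisphere) or `"C"` (Cartesian).
#' @param n_layers number of coupling layers; default 4 for H and 8 for C.
#' @param K spline bins per dimension (K + 1 = 5 knots by default).
#' @param hidden conditioner width.
#' @param n_hidden conditioner depth (hidden layers).
#' @param seed RNG seed for conditioner initialisation.
#' @param clip lower clip for singular log-volume arguments.
#' @return object of class `flow_model`.
#' @export
build_flow_model <- function(frames, kind = c("H", "C"), n_layers = NULL,
                             K = 4L, hidden = 128L, n_hidden = 2L,
                             seed = 1L, clip = 1e-8) {
  kind <- match.arg(kind)
  n_layers <- n_layers %||% if (kind == "H") 4L else 8L
  enc <- fit_flow_encoder(frames, kind, clip = clip)
  masks <- build_coupling_masks(enc$tags, n_layers)
  set.seed(seed)
  layers <- lapply(masks, function(m) {
    make_coupling_layer(enc$D, m, enc$periodic, K = K, hidden = hidden,
                        n_hidden = n_hidden)
  })
  structure(
    list(kind = kind, encoder = enc, layers = layers, n_layers = n_layers,
         K = K, hidden = hidden, n_mol = enc$n_mol, D = enc$D, seed = seed,
         counters = new.env(parent = emptyenv())),
    class = "flow_model"
  )
}

#' Flat base log-density constant
#'
#' Model C: \eqn{\ln p_0 = -3(N-1)\ln 2} (uniform on `[-1, 1]` per retained
#' dimension, `N` the number of real atoms). Model H:
#' \eqn{\ln p_0 = -n_{mol}\ln\pi^2 - (6 n_{mol} - 3)\ln 2}, i.e. uniform on
#' the `q0 >= 0` hemisphere of \eqn{S^3} (surface area \eqn{\pi^2}) per
#' molecule times uniform intervals for the remaining non-rotational
#' degrees of freedom, minus the 3 centre-of-mass dimensions.
#'
#' @param kind `"C"` or `"H"`.
#' @param n_mol number of molecules.
#' @param dims optional explicit dimension count for model C.
#' @return scalar log-density.
#' @export
base_log_density <- function(kind = c("H", "C"), n_mol, dims = NULL) {
  kind <- match.arg(kind)
  if (kind == "C") {
    dims <- dims %||% (9L * n_mol - 3L)
    -dims * log(2)
  } else {
    -n_mol * log(pi^2) - (6L * n_mol - 3L) * log(2)
  }
}

# log base density over z coordinates (per sample), optionally with its
# gradient w.r.t. z. For model H the angle dimensions carry the hemisphere
# surface measure expressed through the fixed affine to [-1, 1].
base_logdens_z <- function(model, z, grad = FALSE) {
  enc <- model$encoder
  B <- nrow(z)
  if (model$kind == "C") {
    val <- rep(-model$D * log(2), B)
    return(if (grad) list(value = val, grad = matrix(0, B, model$D)) else
             list(value = val))
  }
  n_mol <- model$n_mol
  n_uni <- model$D - 3L * n_mol
  const <- n_mol * (-log(pi^2) + log(pi / 4) + log(pi / 2) + log(pi)) -
    n_uni * log(2)
  val <- rep(const, B)
  g <- if (grad) matrix(0, B, model$D) else NULL
  gain <- enc$shift_scale$gain
  lo <- enc$shift_scale$lo
  for (m in seq_len(n_mol)) {
    c0 <- enc$ang_cols[m, 1]; c1 <- enc$ang_cols[m, 2]
    t0 <- (z[, c0] + 1) / gain[c0] + lo[c0]
    t1 <- (z[, c1] + 1) / gain[c1] + lo[c1]
    s0 <- sin(t0); s1 <- sin(t1)
    arg <- s0^2 * s1
    clipped <- arg < enc$clip
    val <- val + log(pmax(arg, enc$clip))
    if (grad) {
      gt0 <- ifelse(clipped, 0, 2 * cos(t0) / pmax(s0, 1e-300)) / gain[c0]
      gt1 <- ifelse(clipped, 0, cos(t1) / pmax(s1, 1e-300)) / gain[c1]
      g[, c0] <- gt0
      g[, c1] <- gt1
    }
  }
  if (grad) list(value = val, grad = g) else list(value = val)
}

# full coupling stack
flow_forward <- function(model, x, keep_cache = FALSE) {
  B <- nrow(x)
  logdet <- numeric(B)
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  n_outside <- 0L
  for (l in seq_along(model$layers)) {
    fw <- coupling_forward(model$layers[[l]], x, keep_cache = keep_cache)
    x <- fw$y
    logdet <- logdet + fw$logdet
    n_outside <- n_outside + fw$n_outside
    if (keep_cache) caches[[l]] <- fw$cache
  }
  if (n_outside > 0L) {
    model$counters$n_outside <- (model$counters$n_outside %||% 0L) + n_outside
  }
  list(z = x, logdet = logdet, caches = caches, n_outside = n_outside)
}

flow_inverse <- function(model, z) {
  B <- nrow(z)
  logdet <- numeric(B)
  for (l in rev(seq_along(model$layers))) {
    iv <- coupling_inverse(model$layers[[l]], z)
    z <- iv$x
    logdet <- logdet + iv$logdet
  }
  list(x = z, logdet = logdet)
}

#' Exact normalized log-probability of supercell configurations
#'
#' \eqn{\ln q(r) = \ln p_0(z(r)) + \ln\gamma_{r\to z}(r)}: the flat base
#' log-density at the mapped point plus the exact accumulated log-volume of
#' the representation, whitening, shift-scale and coupling layers.
#'
#' @param model a [build_flow_model()] flow.
#' @param frames a [supercell_frames()] ensemble (virtual sites are dropped
#'   automatically).
#' @return numeric vector of per-frame log-probabilities.
#' @export
flow_log_prob <- function(model, frames) {
  enc <- encode_frames(model$encoder, frames)
  fw <- flow_forward(model, enc$x)
  bl <- base_logdens_z(model, fw$z)
  bl$value + fw$logdet + enc$log_volume
}

#' Sample supercell configurations from the flow
#'
#' Draws base variates (uniform per dimension; for model H a uniform
#' rotation on the hemisphere of S^3 for each molecule's angle block),
#' applies the inverse coupling stack and decodes to Cartesian frames. The
#' returned `log_q` values are accumulated during generation and match
#' [flow_log_prob()] on the generated frames.
#'
#' @param model a flow model.
#' @param n number of samples.
#' @param temperature temperature tag for the generated ensemble.
#' @return list with `frames`, `log_q`, and the base points `z`.
#' @export
flow_sample <- function(model, n, temperature = NULL) {
  enc <- model$encoder
  z <- matrix(runif(n * model$D, -1, 1), n, model$D)
  if (model$kind == "H") {
    for (m in seq_len(model$n_mol)) {
      q <- runif_hemisphere_quat(n)
      ang <- quat_to_hyperspherical(q, clip = enc$clip)$angles
      cols <- enc$ang_cols[m, ]
      for (j in 1:3) {
        z[, cols[j]] <- (ang[, j] - enc$shift_scale$lo[cols[j]]) *
          enc$shift_scale$gain[cols[j]] - 1
      }
    }
  }
  bl <- base_logdens_z(model, z)
  iv <- flow_inverse(model, z)
  dec <- decode_x(enc, iv$x, temperature = temperature)
  list(frames = dec$frames,
       log_q = bl$value - iv$logdet - dec$log_volume,
       z = z, x = iv$x)
}

#' Round-trip inversion accuracy report
#'
#' Maps frames to the base space and back, reporting the maximum and mean
#' Cartesian inversion error and the forward/inverse log-volume mismatch,
#' together with the number of frames touching a clipped hemisphere
#' singularity. Acceptance thresholds (configurable) follow the package's
#' inversion-accuracy checks: 1e-5 nm on coordinates and 1e-6 on log-volumes.
#'
#' @param model a flow model.
#' @param frames frames to check.
#' @param coord_tol,logvol_tol acceptance thresholds.
#' @return a one-row [tibble::tibble()].
#' @export
roundtrip_report <- function(model, frames, coord_tol = 1e-5,
                             logvol_tol = 1e-6) {
  if (any(frames$roles == "M")) frames <- drop_virtual_site(frames)
  frames <- remove_oxygen_com(frames)
  enc <- encode_frames(model$encoder, frames)
  fw <- flow_forward(model, enc$x)
  iv <- flow_inverse(model, fw$z)
  dec <- decode_x(model$encoder, iv$x)
  derr <- abs(dec$frames$coords - frames$coords)
  # total chain: r->z log-volume is enc + fw; z->r is iv + dec; must cancel
  lv_total <- abs((enc$log_volume + fw$logdet) + (iv$logdet + dec$log_volume))
  tibble(
    n_frames = n_frames(frames),
    max_coord_error = max(derr),
    mean_coord_error = mean(derr),
    max_logvol_mismatch = max(lv_total),
    mean_logvol_mismatch = mean(lv_total),
    n_singular = enc$n_singular,
    pass = max(derr) < coord_tol && max(lv_total) < logvol_tol
  )
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf(
    "<flow_model %s> %d molecules, %d marginal dims, %d coupling layers (%d knots)\n",
    x$kind, x$n_mol, x$D, x$n_layers, x$K + 1L
  ))
  invisible(x)
}

# flat list of trainable parameters (per layer: W list + b list)
flow_params <- function(model) {
  lapply(model$layers, function(l) list(W = l$mlp$W, b = l$mlp$b))
}

flow_set_params <- function(model, params) {
  for (l in seq_along(model$layers)) {
    model$layers[[l]]$mlp$W <- params[[l]]$W
    model$layers[[l]]$mlp$b <- params[[l]]$b
  }
  model
}
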