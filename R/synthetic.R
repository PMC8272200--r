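#' Specify an external object on the mattress
#'
#' External objects (pillows, wedges) present as broad, low-relief pressure
#' plateaus, in contrast to the narrow high bumps produced by bony
#' prominences; that statistical contrast is what the trend-decomposition
#' removal exploits. The footprint must span at least 4 x 4 sensels and the
#' relief must stay below the largest landmark peak of the scene.
#'
#' @param rows,cols integer ranges (e.g. `10:25`) giving the rectangular
#'   footprint of the object on the grid.
#' @param relief plateau height, mmHg.
#' @param edge_softness sensels of smooth taper at the plateau edges.
#' @return an `object_spec`.
#' @export
object_spec <- function(rows, cols, relief = 50, edge_softness = 3) {
  if (length(rows) < 4 || length(cols) < 4) {
    stop("object footprint must span at least 4 x 4 sensels")
  }
  if (relief <= 0) stop("object relief must be positive")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 relief = relief, edge_softness = edge_softness),
            class = "object_spec")
}

# Default landmark tables. Rows are placed at fixed fractions of the grid
# length (head 0.08, shoulders 0.22, sacrum 0.55, feet 0.92); peaks are
# typical bony-prominence interface pressures on a hospital mat, well inside
# the [0, 1000] mmHg capture range. Lateral postures shift the body axis to
# one side, keep a single (loaded) shoulder and stack the feet.
default_landmarks <- function(posture, grid_shape) {
  R <- grid_shape[1]; C <- grid_shape[2]
  mid <- C / 2
  rr <- function(fr) round(fr * R)
  if (posture == "supine") {
    data.frame(
      name   = c("head", "left_shoulder", "right_shoulder", "sacrum",
                 "left_foot", "right_foot"),
      row    = c(rr(0.08), rr(0.22), rr(0.22), rr(0.55), rr(0.92), rr(0.92)),
      col    = round(c(mid, mid - 0.22 * C, mid + 0.22 * C, mid,
                       mid - 0.12 * C, mid + 0.12 * C)),
      peak   = c(220, 180, 180, 300, 150, 150),
      spread = c(2.5, 3.5, 3.5, 4.0, 2.0, 2.0),
      stringsAsFactors = FALSE
    )
  } else {
    side <- if (posture == "left_lateral") -1 else 1
    ax <- mid + side * 0.12 * C
    shoulder <- if (posture == "left_lateral") "left_shoulder" else "right_shoulder"
    foot <- if (posture == "left_lateral") "left_foot" else "right_foot"
    # side-lying concentrates the load on smaller contacts (shoulder,
    # greater trochanter, lateral malleolus): narrower spreads, higher peaks
    data.frame(
      name   = c("head", shoulder, "sacrum", foot),
      row    = c(rr(0.08), rr(0.25), rr(0.55), rr(0.92)),
      col    = round(c(ax, ax + side * 0.08 * C, ax, ax - side * 0.04 * C)),
      peak   = c(220, 320, 380, 180),
      spread = c(2.2, 2.5, 3.0, 1.8),
      stringsAsFactors = FALSE
    )
  }
}

#' Specify a synthetic pressure scene
#'
#' A scene is a body phantom (a set of isotropic bell-shaped pressure bumps,
#' one per high-risk landmark), optional external-object plateaus and
#' additive Gaussian sensor noise, on the default 64 x 32 sensel grid.
#' Landmarks default to the posture's canonical layout: head, shoulders,
#' sacrum and feet for supine; the lateral postures drop the unloaded
#' shoulder and offset the body axis.
#'
#' Optionally the phantom can carry a low body ridge — an elongated pressure
#' elevation following the path through the landmarks — emulating the
#' continuous trunk/leg contact of a real body. It is off by default: a
#' broad low ridge is statistically the same kind of signal as an external
#' object, so scenes with it probe the documented failure regime of the
#' trend-based removal rather than its intended operating regime.
#'
#' @param posture one of `"supine"`, `"left_lateral"`, `"right_lateral"`.
#' @param landmarks data frame with columns `name`, `row`, `col`, `peak`
#'   (mmHg) and `spread` (sensels); `NULL` for the posture default. An empty
#'   (0-row) data frame yields a body-free scene.
#' @param objects list of [object_spec()]s.
#' @param noise_sd standard deviation of the additive sensor noise, mmHg.
#' @param seed integer seed; scenes are deterministic given the spec.
#' @param ridge_amp peak height of the body ridge, mmHg (0 disables it).
#' @param ridge_sigma half-width (Gaussian sigma, sensels) of the ridge
#'   across the body axis; `NULL` picks 5 for supine, 4 for lateral (a body
#'   on its side presents a narrower contact strip).
#' @param grid_shape integer `c(rows, cols)`.
#' @param sensor_max capture ceiling, mmHg.
#' @return a `scene_spec`.
#' @export
scene_spec <- function(posture = "supine", landmarks = NULL, objects = list(),
                       noise_sd = 5, seed = 1, ridge_amp = 0,
                       ridge_sigma = NULL, grid_shape = c(64L, 32L),
                       sensor_max = 1000) {
  posture <- match.arg(posture, c("supine", "left_lateral", "right_lateral"))
  if (is.null(landmarks)) landmarks <- default_landmarks(posture, grid_shape)
  if (nrow(landmarks) > 0) {
    if (any(landmarks$row < 1 | landmarks$row > grid_shape[1] |
            landmarks$col < 1 | landmarks$col > grid_shape[2])) {
      stop("landmark coordinates must lie inside the grid")
    }
    if (any(landmarks$peak <= 0 | landmarks$peak > sensor_max)) {
      stop("landmark peaks must lie in (0, sensor_max]")
    }
    if (any(landmarks$spread < 1)) stop("landmark spread must be >= 1 sensel")
    max_peak <- max(landmarks$peak)
    for (ob in objects) {
      if (ob$relief >= max_peak) {
        stop("object relief must stay below the largest landmark peak")
      }
    }
  }
  for (ob in objects) {
    if (any(ob$rows < 1 | ob$rows > grid_shape[1]) ||
        any(ob$cols < 1 | ob$cols > grid_shape[2])) {
      stop("object footprint must lie inside the grid")
    }
  }
  if (is.null(ridge_sigma)) ridge_sigma <- if (posture == "supine") 5 else 4
  structure(list(posture = posture, landmarks = landmarks, objects = objects,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 ridge_amp = ridge_amp, ridge_sigma = ridge_sigma,
                 grid_shape = as.integer(grid_shape), sensor_max = sensor_max),
            class = "scene_spec")
}

# Body ridge: a Gaussian strip across the axis that linearly interpolates the
# landmark columns from the head row to the feet row, with a soft taper
# beyond the end landmarks.
ridge_field <- function(spec) {
  gs <- spec$grid_shape
  lms <- spec$landmarks
  if (spec$ridge_amp <= 0 || nrow(lms) < 2) return(matrix(0, gs[1], gs[2]))
  path_pts <- stats::aggregate(col ~ row, data = lms, FUN = mean)
  rows <- seq_len(gs[1])
  path <- if (nrow(path_pts) >= 2) {
    stats::approx(path_pts$row, path_pts$col, xout = rows, rule = 2)$y
  } else {
    rep(path_pts$col[1], gs[1])
  }
  taper <- rep(1, gs[1])
  lo <- min(lms$row); hi <- max(lms$row)
  out <- rows < lo
  taper[out] <- exp(-((lo - rows[out])^2) / (2 * 2^2))
  out <- rows > hi
  taper[out] <- exp(-((rows[out] - hi)^2) / (2 * 2^2))
  cols <- seq_len(gs[2])
  across <- exp(-outer(path, cols, function(p, c) (c - p)^2) /
                  (2 * spec$ridge_sigma^2))
  spec$ridge_amp * taper * across
}

# Squared-exponential bump centred at (row, col).
blob_field <- function(grid_shape, row, col, peak, spread) {
  r <- seq_len(grid_shape[1]); c <- seq_len(grid_shape[2])
  d2 <- outer((r - row)^2, (c - col)^2, `+`)
  peak * exp(-d2 / (2 * spread^2))
}

# Plateau with smooth (cosine-tapered) edges.
object_field <- function(grid_shape, ob) {
  taper <- function(idx, span, soft) {
    w <- numeric(length(idx))
    lo <- min(span); hi <- max(span)
    inside <- idx >= lo & idx <= hi
    w[inside] <- 1
    if (soft > 0) {
      d <- pmin(idx[inside] - lo, hi - idx[inside])
      edge <- d < soft
      w[inside][edge] <- 0.5 * (1 - cos(pi * (d[edge] + 1) / (soft + 1)))
    }
    w
  }
  wr <- taper(seq_len(grid_shape[1]), ob$rows, ob$edge_softness)
  wc <- taper(seq_len(grid_shape[2]), ob$cols, ob$edge_softness)
  ob$relief * outer(wr, wc)
}

# Noise-free components of a scene; shared by generate_scene/generate_sequence.
scene_fields <- function(spec) {
  gs <- spec$grid_shape
  body <- matrix(0, gs[1], gs[2])
  if (nrow(spec$landmarks) > 0) {
    for (i in seq_len(nrow(spec$landmarks))) {
      lm <- spec$landmarks[i, ]
      body <- body + blob_field(gs, lm$row, lm$col, lm$peak, lm$spread)
    }
    body <- body + ridge_field(spec)
  }
  object <- matrix(0, gs[1], gs[2])
  for (ob in spec$objects) object <- object + object_field(gs, ob)
  list(body = body, object = object)
}

# Mask level: a sensel belongs to the body/object mask when its noise-free
# contribution exceeds this pressure (mmHg). Chosen at the sensor noise scale
# so masks hug the visible footprint.
MASK_LEVEL <- 5

#' Generate one synthetic pressure frame with ground truth
#'
#' The frame is `clip(body bumps + object plateaus + noise, 0, sensor_max)`.
#' The ground truth carries the body mask, object mask, landmark table,
#' posture label and the noise-free body and object fields, which the test
#' suite and the acceptance bench use as oracles.
#'
#' @param spec a [scene_spec()].
#' @return list with elements `frame` (a [pressure_frame()]) and `truth`
#'   (a `scene_ground_truth`).
#' @export
generate_scene <- function(spec) {
  fields <- scene_fields(spec)
  gs <- spec$grid_shape
  clean <- fields$body + fields$object
  noise <- if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    matrix(rnorm(prod(gs), 0, spec$noise_sd), gs[1], gs[2])
  } else {
    matrix(0, gs[1], gs[2])
  }
  values <- pmin(pmax(clean + noise, 0), spec$sensor_max)
  truth <- structure(list(
    body_mask = fields$body > MASK_LEVEL,
    object_mask = fields$object > MASK_LEVEL,
    overlap = (fields$body > MASK_LEVEL) & (fields$object > MASK_LEVEL),
    landmarks = spec$landmarks,
    posture = spec$posture,
    body_field = fields$body,
    object_field = fields$object
  ), class = "scene_ground_truth")
  list(frame = pressure_frame(values, sensor_max = spec$sensor_max),
       truth = truth)
}

#' Generate a synthetic sequence (static body, per-frame noise)
#'
#' Emulates a short mattress recording of a patient who does not move: the
#' noise-free scene is constant while each frame gets independent sensor
#' noise plus a slow random-walk drift of the global mean. Ground truth is
#' the same for every frame.
#'
#' @param spec a [scene_spec()].
#' @param n_frames number of frames (>= 1).
#' @param drift_sd per-frame standard deviation of the mean-drift random
#'   walk, mmHg; 0 disables drift.
#' @param sampling_hz sampling rate.
#' @return list with elements `sequence` (a [pressure_sequence()]) and
#'   `truth`.
#' @export
generate_sequence <- function(spec, n_frames, drift_sd = 0, sampling_hz = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  fields <- scene_fields(spec)
  gs <- spec$grid_shape
  clean <- fields$body + fields$object
  set.seed(spec$seed)
  drift <- if (drift_sd > 0) cumsum(rnorm(n_frames, 0, drift_sd)) else numeric(n_frames)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    noise <- if (spec$noise_sd > 0) {
      matrix(rnorm(prod(gs), 0, spec$noise_sd), gs[1], gs[2])
    } else {
      matrix(0, gs[1], gs[2])
    }
    values <- pmin(pmax(clean + drift[k] + noise, 0), spec$sensor_max)
    frames[[k]] <- pressure_frame(values, sensor_max = spec$sensor_max)
  }
  truth <- generate_scene(within_spec_no_noise(spec))$truth
  list(sequence = pressure_sequence(frames, sampling_hz = sampling_hz,
                                    subject_id = paste0("synthetic-", spec$seed),
                                    pose_id = spec$posture),
       truth = truth)
}

within_spec_no_noise <- function(spec) {
  spec$noise_sd <- 0
  spec
}

#' Generate a balanced labelled posture dataset
#'
#' Builds a three-class set (supine / left lateral / right lateral) of
#' synthetic frames for training and evaluating posture classifiers. Each
#' sample belongs to one of `n_subjects` synthetic subjects; a subject
#' carries a persistent anatomical perturbation (landmark positions, peak
#' pressures, body-axis offset) on top of which every frame adds a small
#' per-frame jitter, so that frames of one subject are correlated and
#' subject-wise train/test splits are meaningful. Sub-seeds are derived
#' per sample, so the dataset is reproducible from `seed` alone.
#'
#' @param n_per_posture frames per class (>= 1).
#' @param jitter list of perturbation ranges: `subject_shift_row` /
#'   `subject_shift_col` (sensels, sd of the per-subject landmark
#'   displacement along and across the bed; the longitudinal component is
#'   larger — body height varies more than lateral placement, since patients
#'   are positioned near the mat centre), `max_col_shift` (sensels, clamp on
#'   the per-subject lateral offset), `frame_shift` (sensels, sd of the
#'   per-frame displacement emulating small in-recording movements),
#'   `peak_frac` (relative sd of peak scaling).
#' @param seed integer master seed.
#' @param n_subjects synthetic subjects per class pool (subjects are shared
#'   across classes, as real subjects adopt all postures).
#' @param noise_sd sensor noise, mmHg.
#' @param grid_shape grid dimensions.
#' @return list of samples, each `list(frame, label, subject_id)`.
#' @export
labelled_dataset <- function(n_per_posture, jitter = list(), seed = 1,
                             n_subjects = 13, noise_sd = 5,
                             grid_shape = c(64L, 32L)) {
  if (n_per_posture < 1) stop("n_per_posture must be >= 1")
  j <- utils::modifyList(list(subject_shift_row = 2.0, subject_shift_col = 1.0,
                              max_col_shift = 2.0, frame_shift = 1.2,
                              peak_frac = 0.10), jitter)
  postures <- c("supine", "left_lateral", "right_lateral")

  # Persistent per-subject anatomy: one displacement/scale draw per subject.
  set.seed(seed)
  subj <- lapply(seq_len(n_subjects), function(s) {
    # lateral placement is clamped: staff centre patients on the mat, so a
    # body never starts more than ~2 sensels (5 cm) off its posture's axis
    list(dr = rnorm(1, 0, j$subject_shift_row),
         dc = max(-j$max_col_shift,
                  min(j$max_col_shift, rnorm(1, 0, j$subject_shift_col))),
         scale = exp(rnorm(1, 0, j$peak_frac)))
  })

  samples <- list()
  idx <- 0
  for (p in seq_along(postures)) {
    for (k in seq_len(n_per_posture)) {
      idx <- idx + 1
      s <- ((k - 1) %% n_subjects) + 1
      sub_seed <- (seed * 100003 + idx * 257) %% 2147483647L
      set.seed(sub_seed)
      lms <- default_landmarks(postures[p], grid_shape)
      lms$row <- pmax(2, pmin(grid_shape[1] - 1, round(
        lms$row + subj[[s]]$dr + rnorm(nrow(lms), 0, j$frame_shift))))
      lms$col <- pmax(2, pmin(grid_shape[2] - 1, round(
        lms$col + subj[[s]]$dc + rnorm(nrow(lms), 0, j$frame_shift))))
      lms$peak <- lms$peak * subj[[s]]$scale *
        exp(rnorm(nrow(lms), 0, j$peak_frac / 2))
      lms$peak <- pmin(lms$peak, 1000)
      sp <- scene_spec(postures[p], landmarks = lms, noise_sd = noise_sd,
                       seed = sub_seed, grid_shape = grid_shape)
      sc <- generate_scene(sp)
      samples[[idx]] <- list(frame = sc$frame, label = postures[p],
                             subject_id = sprintf("S%02d", s))
    }
  }
  samples
}
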