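#' Accession specification for the synthetic rosette generator
#'
#' An accession spec bundles the growth-dynamics and appearance parameters of
#' one synthetic genotype class: how fast leaves are added and expand, leaf
#' shape (length/width aspect), foreground hue distribution, and the
#' phyllotactic angle between successive leaves.
#'
#' @param name character label.
#' @param leaf_add_schedule function mapping plant age in days (>= 0) to the
#'   cumulative number of leaves; must be non-decreasing and integer-valued.
#' @param expansion_rate leaf major-axis growth in pixels/day at the reference
#'   256 px canvas (> 0).
#' @param leaf_aspect leaf length/width ratio (>= 1).
#' @param hue_center,hue_jitter foreground hue distribution (HSV degrees);
#'   each plant draws one hue offset ~ N(0, hue_jitter).
#' @param rotation_phyllotaxy angular offset between consecutive leaves, degrees.
#' @param leaf_base_length,leaf_max_length leaf length at age 0 and its cap,
#'   pixels at the reference 256 px canvas.
#' @return an object of class `accession_spec`.
#' @export
accession_spec <- function(name, leaf_add_schedule, expansion_rate, leaf_aspect,
                           hue_center, hue_jitter = 6, rotation_phyllotaxy = 137.5,
                           leaf_base_length = 6, leaf_max_length = 80) {
  stopifnot(is.character(name), length(name) == 1L, is.function(leaf_add_schedule))
  probe <- leaf_add_schedule(0:60)
  if (any(diff(probe) < 0)) stop("leaf_add_schedule must be non-decreasing", call. = FALSE)
  if (any(probe < 0) || any(probe != round(probe)))
    stop("leaf_add_schedule must be a non-negative integer function", call. = FALSE)
  if (expansion_rate <= 0) stop("expansion_rate must be > 0", call. = FALSE)
  if (leaf_aspect < 1) stop("leaf_aspect must be >= 1", call. = FALSE)
  structure(list(name = name, leaf_add_schedule = leaf_add_schedule,
                 expansion_rate = expansion_rate, leaf_aspect = leaf_aspect,
                 hue_center = hue_center, hue_jitter = hue_jitter,
                 rotation_phyllotaxy = rotation_phyllotaxy,
                 leaf_base_length = leaf_base_length,
                 leaf_max_length = leaf_max_length),
            class = "accession_spec")
}

#' @export
print.accession_spec <- function(x, ...) {
  cat(sprintf("<accession_spec '%s'> rate %.1f px/d, aspect %.1f, hue %.0f deg, phyllotaxy %.1f deg\n",
              x$name, x$expansion_rate, x$leaf_aspect, x$hue_center, x$rotation_phyllotaxy))
  invisible(x)
}

#' Leaf-addition schedule builder
#'
#' Returns a non-decreasing step function: no leaves before `start` days, then
#' one leaf every `interval` days up to `cap` leaves.
#'
#' @param interval days between successive leaf initiations.
#' @param cap maximum leaf count.
#' @param start age (days) at which the first leaf appears.
#' @return a vectorised function of age in days.
#' @export
leaf_schedule <- function(interval, cap, start = 1) {
  force(interval); force(cap); force(start)
  function(day) pmin(cap, pmax(0, floor((day - start) / interval) + 1))
}

#' Built-in accession panels
#'
#' `default_accession_panel()` is the benchmark panel of four classes. Classes
#' 1 and 2 share every static appearance parameter and differ only in growth
#' dynamics (leaf-addition schedule and expansion rate), so dynamics-only
#' discrimination experiments can be built from them; classes 3 and 4 differ
#' from the first pair and from each other mainly in phyllotactic arrangement,
#' with subtle hue and leaf-aspect offsets that overlap under the per-plant hue
#' jitter. `easy_accession_panel()` separates all four classes strongly in hue,
#' shape and dynamics and is used for segmentation fixtures and sanity checks.
#' `dynamics_panel()` is the dynamics-only pair (classes 1-2 of the default
#' panel).
#'
#' @return a list of [accession_spec()] objects.
#' @export
default_accession_panel <- function() {
  list(
    accession_spec("dyn-fast", leaf_schedule(1.6, 13), expansion_rate = 8,
                   leaf_aspect = 2.6, hue_center = 95, hue_jitter = 6,
                   rotation_phyllotaxy = 137.5),
    accession_spec("dyn-slow", leaf_schedule(2.8, 9), expansion_rate = 5,
                   leaf_aspect = 2.6, hue_center = 95, hue_jitter = 6,
                   rotation_phyllotaxy = 137.5),
    accession_spec("round-cross", leaf_schedule(2.1, 11), expansion_rate = 6.5,
                   leaf_aspect = 2.2, hue_center = 103, hue_jitter = 6,
                   rotation_phyllotaxy = 90),
    accession_spec("narrow-spiral", leaf_schedule(2.1, 11), expansion_rate = 6.5,
                   leaf_aspect = 3.0, hue_center = 87, hue_jitter = 6,
                   rotation_phyllotaxy = 72)
  )
}

#' @rdname default_accession_panel
#' @export
easy_accession_panel <- function() {
  list(
    accession_spec("easy-1", leaf_schedule(1.6, 13), expansion_rate = 8,
                   leaf_aspect = 1.6, hue_center = 85, hue_jitter = 3,
                   rotation_phyllotaxy = 137.5),
    accession_spec("easy-2", leaf_schedule(2.4, 10), expansion_rate = 6,
                   leaf_aspect = 2.4, hue_center = 105, hue_jitter = 3,
                   rotation_phyllotaxy = 90),
    accession_spec("easy-3", leaf_schedule(2.0, 12), expansion_rate = 7,
                   leaf_aspect = 3.2, hue_center = 65, hue_jitter = 3,
                   rotation_phyllotaxy = 72),
    accession_spec("easy-4", leaf_schedule(3.0, 8), expansion_rate = 5,
                   leaf_aspect = 2.0, hue_center = 125, hue_jitter = 3,
                   rotation_phyllotaxy = 144)
  )
}

#' @rdname default_accession_panel
#' @export
dynamics_panel <- function() default_accession_panel()[1:2]

#' Render one synthetic rosette frame
#'
#' Draws a centred rosette of rotated filled ellipses (one per leaf) over a
#' soil-textured background of low-frequency brown noise plus speckle, and
#' returns the frame together with its ground-truth foreground mask. All
#' randomness (soil texture, per-plant rotation, leaf-angle and length jitter,
#' hue offsets, foreground texture) derives from `seed` and is drawn
#' independently of `day`, so frames of the same plant are consistent across
#' days and the output is deterministic for a fixed `(spec, day, seed)`.
#'
#' @param spec an [accession_spec()].
#' @param day plant age in days (>= 0); the leaf-addition schedule and
#'   expansion rate are evaluated at this age.
#' @param canvas_size side of the square canvas in pixels (>= 64; default 256).
#' @param seed integer seed for the plant-level random stream.
#' @return list with `frame` (H x W x 3 array in `[0,1]`) and `mask`
#'   (logical matrix marking rendered foreground pixels).
#' @export
render_frame <- function(spec, day, canvas_size = 256, seed = 1) {
  stopifnot(inherits(spec, "accession_spec"))
  if (canvas_size < 64) stop("canvas_size must be >= 64", call. = FALSE)
  day <- max(0, day)
  s <- canvas_size
  scale <- s / 256
  max_leaves <- 40L

  with_local_seed(seed, {
    coarse <- matrix(rnorm(64), 8, 8)
    spk <- matrix(runif(s * s) - 0.5, s, s)
    angle_jit <- rnorm(max_leaves, 0, 6)
    len_jit <- rnorm(max_leaves, 0, 0.10)
    leaf_hue <- rnorm(max_leaves, 0, 2)
    plant_hue <- rnorm(1, 0, spec$hue_jitter)
    plant_sat <- 0.55 + rnorm(1, 0, 0.05)
    plant_val <- 0.45 + rnorm(1, 0, 0.05)
    rot_global <- runif(1, 0, 360)
    center_jit <- runif(2, -4, 4) * scale
    tex <- matrix(rnorm(s * s, 0, 0.045), s, s)
  })

  low <- array(as.numeric(EBImage::resize(coarse, w = s, h = s)), c(s, s))
  r <- clamp01(0.46 + 0.08 * low + 0.05 * spk)
  g <- clamp01(0.34 + 0.065 * low + 0.04 * spk)
  b <- clamp01(0.23 + 0.05 * low + 0.03 * spk)
  frame <- array(c(r, g, b), c(s, s, 3L))
  mask <- matrix(FALSE, s, s)

  n_leaves <- spec$leaf_add_schedule(day)
  if (n_leaves > 0) {
    counts <- spec$leaf_add_schedule(0:day)
    cy <- s / 2 + center_jit[1]
    cx <- s / 2 + center_jit[2]
    n_leaves <- min(n_leaves, max_leaves)
    # furthest possible leaf-tip radius this day; error if the canvas cannot hold it
    lens <- vapply(seq_len(n_leaves), function(k) {
      birth <- which(counts >= k)[1] - 1L
      age <- day - birth
      min(spec$leaf_max_length, spec$leaf_base_length + spec$expansion_rate * age) *
        (1 + len_jit[k]) * scale
    }, numeric(1))
    if (0.95 * max(lens) + max(abs(center_jit)) > s / 2 - 1)
      stop("canvas too small to hold the plant at this day", call. = FALSE)

    sat <- clamp01(plant_sat)
    val0 <- clamp01(plant_val)
    for (k in seq_len(n_leaves)) {
      a <- lens[k] / 2
      if (a < 0.8) next
      bx <- max(a / spec$leaf_aspect, 0.6)
      theta <- (rot_global + (k - 1) * spec$rotation_phyllotaxy + angle_jit[k]) * pi / 180
      ecy <- cy + 0.9 * a * sin(theta)
      ecx <- cx + 0.9 * a * cos(theta)
      rr <- max(1L, floor(ecy - a - 1)):min(s, ceiling(ecy + a + 1))
      cc <- max(1L, floor(ecx - a - 1)):min(s, ceiling(ecx + a + 1))
      dy <- rr - ecy
      dx <- cc - ecx
      u <- outer(dy, dx, function(y, x) y * sin(theta) + x * cos(theta))
      v <- outer(dy, dx, function(y, x) -y * cos(theta) + x * sin(theta))
      inside <- (u / a)^2 + (v / bx)^2 <= 1
      if (!any(inside)) next
      hue <- (spec$hue_center + plant_hue + leaf_hue[k]) %% 360
      base <- as.numeric(grDevices::col2rgb(grDevices::hsv(hue / 360, sat, val0))) / 255
      idx <- which(inside, arr.ind = TRUE)
      pr <- rr[idx[, 1]]
      pc <- cc[idx[, 2]]
      lin <- cbind(pr, pc)
      vals <- clamp01(val0 + tex[lin])
      fac <- vals / val0
      for (ch in 1:3) frame[cbind(pr, pc, ch)] <- clamp01(base[ch] * fac)
      mask[lin] <- TRUE
    }
  }
  list(frame = frame, mask = mask)
}

#' Plant sequence container
#'
#' Holds one plant's ordered daily frames, genotype label, day indices, and
#' (optionally) ground-truth masks.
#'
#' @param plant_id character id.
#' @param genotype 0-based class index.
#' @param frames list of RGB arrays, all the same size.
#' @param day_index integer vector, strictly increasing, one entry per frame.
#' @param truth_masks optional list of logical matrices aligned with `frames`.
#' @return an object of class `plant_sequence`.
#' @export
plant_sequence <- function(plant_id, genotype, frames, day_index, truth_masks = NULL) {
  stopifnot(length(frames) == length(day_index))
  if (any(diff(day_index) <= 0)) stop("day_index must be strictly increasing", call. = FALSE)
  d1 <- dim(frames[[1]])
  for (f in frames) {
    assert_rgb(f)
    if (!all(dim(f) == d1)) stop("all frames must share one size", call. = FALSE)
  }
  if (!is.null(truth_masks)) {
    stopifnot(length(truth_masks) == length(frames))
    for (m in truth_masks) assert_mask(m, frames[[1]])
  }
  structure(list(plant_id = plant_id, genotype = as.integer(genotype),
                 frames = frames, day_index = as.integer(day_index),
                 truth_masks = truth_masks),
            class = "plant_sequence")
}

#' @export
print.plant_sequence <- function(x, ...) {
  cat(sprintf("<plant_sequence '%s'> genotype %d, %d frames (days %d-%d), %s truth masks\n",
              x$plant_id, x$genotype, length(x$frames), min(x$day_index),
              max(x$day_index), if (is.null(x$truth_masks)) "no" else "with"))
  invisible(x)
}

#' Generate an in-memory synthetic time-lapse dataset
#'
#' Renders `n_plants_per_class` plants for every accession in `panel`, each a
#' fixed-length daily sequence with ground-truth masks. Replicates of a class
#' differ through a per-plant random germination offset (uniform on 0-3 days),
#' a random whole-rosette rotation, leaf-angle/length jitter, and a per-plant
#' hue offset.
#'
#' @param panel list of [accession_spec()] objects.
#' @param n_plants_per_class plants per accession (>= 1).
#' @param n_days frames per plant (default 22, one per day).
#' @param canvas_size canvas side in pixels.
#' @param seed integer master seed; the dataset is reproduced byte-for-byte.
#' @return list with `sequences` (list of [plant_sequence()]) and `manifest`
#'   (tibble: plant_id, genotype_name, genotype_index, germination_offset).
#' @export
generate_sequences <- function(panel, n_plants_per_class, n_days = 22,
                               canvas_size = 256, seed = 1) {
  stopifnot(n_plants_per_class >= 1)
  n_total <- length(panel) * n_plants_per_class
  with_local_seed(seed, {
    plant_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
    offsets <- sample(0:3, n_total, replace = TRUE)
  })
  seqs <- vector("list", n_total)
  man <- vector("list", n_total)
  i <- 0L
  for (ci in seq_along(panel)) {
    spec <- panel[[ci]]
    for (p in seq_len(n_plants_per_class)) {
      i <- i + 1L
      pid <- sprintf("c%d_%s_p%02d", ci - 1L, spec$name, p)
      rendered <- lapply(seq_len(n_days), function(d)
        render_frame(spec, day = d - 1L - offsets[i], canvas_size = canvas_size,
                     seed = plant_seeds[i]))
      seqs[[i]] <- plant_sequence(
        plant_id = pid, genotype = ci - 1L,
        frames = lapply(rendered, `[[`, "frame"),
        day_index = seq_len(n_days),
        truth_masks = lapply(rendered, `[[`, "mask"))
      man[[i]] <- tibble::tibble(plant_id = pid, genotype_name = spec$name,
                                 genotype_index = ci - 1L,
                                 germination_offset = offsets[i])
    }
  }
  list(sequences = seqs, manifest = dplyr::bind_rows(man))
}

#' Write a synthetic dataset to disk
#'
#' One directory per plant holding `n_days` PNG frames and truth masks, plus a
#' tab-separated manifest (plant_id, genotype_name, genotype_index, day,
#' frame_path, mask_path) at the dataset root.
#'
#' @inheritParams generate_sequences
#' @param out_dir output directory (created if missing).
#' @return the per-frame manifest tibble, invisibly.
#' @export
generate_dataset <- function(panel, n_plants_per_class, out_dir, n_days = 22,
                             canvas_size = 256, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  ds <- generate_sequences(panel, n_plants_per_class, n_days, canvas_size, seed)
  rows <- list()
  for (sq in ds$sequences) {
    pdir <- file.path(out_dir, sq$plant_id)
    dir.create(pdir, showWarnings = FALSE)
    for (j in seq_along(sq$frames)) {
      fp <- file.path(sq$plant_id, sprintf("frame_d%02d.png", sq$day_index[j]))
      mp <- file.path(sq$plant_id, sprintf("mask_d%02d.png", sq$day_index[j]))
      write_frame(sq$frames[[j]], file.path(out_dir, fp))
      write_mask(sq$truth_masks[[j]], file.path(out_dir, mp))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        plant_id = sq$plant_id,
        genotype_name = ds$manifest$genotype_name[match(sq$plant_id, ds$manifest$plant_id)],
        genotype_index = sq$genotype, day = sq$day_index[j],
        frame_path = fp, mask_path = mp)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param dir dataset root containing `manifest.tsv`.
#' @return list with `sequences` and the per-frame `manifest` tibble.
#' @export
read_dataset <- function(dir) {
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"), show_col_types = FALSE)
  seqs <- lapply(split(manifest, manifest$plant_id), function(mf) {
    mf <- mf[order(mf$day), ]
    plant_sequence(
      plant_id = mf$plant_id[1], genotype = mf$genotype_index[1],
      frames = lapply(file.path(dir, mf$frame_path), read_frame),
      day_index = mf$day,
      truth_masks = lapply(file.path(dir, mf$mask_path), read_mask))
  })
  ord <- order(vapply(seqs, function(s) s$plant_id, character(1)))
  list(sequences = unname(seqs[ord]), manifest = manifest)
}
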