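#' Phantom study specification
#'
#' Parameters of the synthetic IC phantom. Defaults mirror the acquisition
#' the pipeline targets: an 80 x 80 in-plane matrix with 46 axial slices,
#' TR 2 s, 595 usable volumes, roughly 50 ICs per subject of which well
#' under a fifth are SOZ-localising, the rest split between noise (60%)
#' and RSNs (30%).
#'
#' @param grid Integer length-3, `(nx, ny, nslices)`.
#' @param n_ics Number of ICs per subject.
#' @param class_mix Named proportions over `(noise, rsn, soz)`, summing
#'   to 1.
#' @param noise_subtype_mix Named proportions over the four noise
#'   subtypes, summing to 1.
#' @param t_len Time-course length in samples.
#' @param tr_seconds Repetition time (s).
#' @param seed Integer seed controlling every random draw.
#' @param snr Peak activation amplitude divided by voxel noise standard
#'   deviation. The default 8 leaves all marker-recovery properties
#'   attainable without saturating them.
#' @return List of class `"phantom_spec"`.
#' @export
phantom_spec <- function(grid = c(80L, 80L, 46L),
                         n_ics = 50L,
                         class_mix = c(noise = 0.6, rsn = 0.3, soz = 0.1),
                         noise_subtype_mix = c(boundary = 0.25,
                                               white_matter = 0.25,
                                               vessel = 0.25,
                                               small_clusters = 0.25),
                         t_len = 595L,
                         tr_seconds = 2,
                         seed = 1L,
                         snr = 8) {
  stopifnot(length(grid) == 3, all(grid[1:2] >= 16), grid[3] >= 4,
            n_ics >= 1,
            abs(sum(class_mix) - 1) < 1e-9,
            abs(sum(noise_subtype_mix) - 1) < 1e-9,
            all(class_mix >= 0), all(noise_subtype_mix >= 0),
            t_len >= 8, tr_seconds > 0, snr > 0)
  if (!setequal(names(class_mix), c("noise", "rsn", "soz"))) {
    stop("class_mix must be named (noise, rsn, soz)")
  }
  if (!setequal(names(noise_subtype_mix), NOISE_SUBTYPES)) {
    stop("noise_subtype_mix must be named over the four noise subtypes")
  }
  structure(list(
    grid = as.integer(grid), n_ics = as.integer(n_ics),
    class_mix = class_mix[c("noise", "rsn", "soz")],
    noise_subtype_mix = noise_subtype_mix[NOISE_SUBTYPES],
    t_len = as.integer(t_len), tr_seconds = tr_seconds,
    seed = as.integer(seed), snr = snr,
    amp = 5                     # peak activation z-score of phantom blobs
  ), class = "phantom_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

## per-slice ellipse geometry of the phantom head
slice_geometry <- function(grid, s) {
  nx <- grid[1]; ny <- grid[2]; ns <- grid[3]
  t <- (s - (ns + 1) / 2) / (0.6 * ns)
  shrink <- sqrt(max(0.18, 1 - t^2))
  list(cx = (nx + 1) / 2, cy = (ny + 1) / 2,
       rx = 0.42 * nx * shrink, ry = 0.45 * ny * shrink)
}

rho_grid <- function(grid, s) {
  g <- slice_geometry(grid, s)
  x <- matrix(seq_len(grid[1]), grid[1], grid[2])
  y <- matrix(seq_len(grid[2]), grid[1], grid[2], byrow = TRUE)
  sqrt(((x - g$cx) / g$rx)^2 + ((y - g$cy) / g$ry)^2)
}

## mirror-symmetric vessel centres in the basal central region
vessel_centres <- function(grid, s, nv) {
  g <- slice_geometry(grid, s)
  offs <- list(0, c(-1, 1), c(-1, 0, 1))[[nv]]
  lapply(offs, function(k) {
    c(x = g$cx + k * 0.18 * g$rx, y = g$cy - 0.12 * g$ry)
  })
}

disk_mask <- function(grid, centre, r) {
  x <- matrix(seq_len(grid[1]), grid[1], grid[2])
  y <- matrix(seq_len(grid[2]), grid[1], grid[2], byrow = TRUE)
  (x - centre[1])^2 + (y - centre[2])^2 <= r^2
}

#' Generate phantom anatomy
#'
#' Elliptical brain with a smooth slice-wise radius profile, a
#' white-matter annulus, 1–3 mirror-symmetric basal vessel spots and a
#' background intensity image (dim outside, mid-gray cortex/gray matter,
#' bright white matter, dark vessels, light texture noise). The returned
#' ground-truth masks are what the contour module is scored against.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `"phantom_anatomy"`: logical 3D arrays
#'   `periphery`, `white_matter`, `vessels`, `gray_matter`; numeric 3D
#'   `background`; `n_vessels`.
#' @export
generate_anatomy <- function(spec) {
  with_seed(spec$seed, {
    grid <- spec$grid
    nv <- sample(1:3, 1)
    periph <- wm <- ves <- array(FALSE, grid)
    bg <- array(0, grid)
    for (s in seq_len(grid[3])) {
      rho <- rho_grid(grid, s)
      p <- rho <= 1
      w <- rho >= 0.55 & rho <= 0.78
      v <- matrix(FALSE, grid[1], grid[2])
      for (ctr in vessel_centres(grid, s, nv)) {
        v <- v | disk_mask(grid, ctr, 2)
      }
      v <- v & rho < 0.5
      slice_bg <- matrix(0, grid[1], grid[2])
      slice_bg[p] <- 0.7
      slice_bg[w] <- 1.3
      slice_bg[v] <- 0.1
      periph[, , s] <- p; wm[, , s] <- w; ves[, , s] <- v
      bg[, , s] <- slice_bg + matrix(stats::rnorm(prod(grid[1:2]), 0, 0.03),
                                     grid[1], grid[2])
    }
    structure(list(periphery = periph, white_matter = wm, vessels = ves,
                   gray_matter = periph & !wm & !ves,
                   background = bg, n_vessels = nv),
              class = "phantom_anatomy")
  })
}

RSN_NETWORKS <- data.frame(
  name = c("sensorimotor", "language", "parietal", "frontal",
           "temporal", "visual", "default_mode", "deep_gray"),
  rho = c(0.85, 0.85, 0.85, 0.85, 0.88, 0.85, 0.85, 0.25),
  theta_deg = c(-60, -20, 20, -40, 40, 60, 10, 150),
  slice_frac = c(0.75, 0.55, 0.70, 0.65, 0.40, 0.30, 0.60, 0.50),
  stringsAsFactors = FALSE
)

template_centres <- function(grid, s, net) {
  g <- slice_geometry(grid, s)
  th <- net$theta_deg * pi / 180
  dx <- net$rho * g$rx * cos(th)
  dy <- net$rho * g$ry * sin(th)
  list(c(x = g$cx - dx, y = g$cy + dy), c(x = g$cx + dx, y = g$cy + dy))
}

template_band <- function(grid, net) {
  ctr <- round(net$slice_frac * grid[3])
  seq(max(1, ctr - 2), min(grid[3], ctr + 2))
}

#' Schematic RSN templates
#'
#' Deterministic bilateral binary masks for eight canonical resting-state
#' networks (sensorimotor, language, parietal, frontal, temporal, visual,
#' default-mode, deep gray), built on the phantom head geometry of the
#' given grid. Each network is a mirrored pair of disks over a 5-slice
#' band. Real-atlas masks can be substituted anywhere a template list is
#' accepted.
#'
#' @param grid Integer length-3 grid `(nx, ny, nslices)`.
#' @return Named list of 3D logical arrays.
#' @export
generate_templates <- function(grid) {
  r_t <- max(2, round(0.05 * grid[1]))
  out <- list()
  for (i in seq_len(nrow(RSN_NETWORKS))) {
    net <- RSN_NETWORKS[i, ]
    m <- array(FALSE, grid)
    for (s in template_band(grid, net)) {
      for (ctr in template_centres(grid, s, net)) {
        m[, , s] <- m[, , s] | disk_mask(grid, ctr, r_t)
      }
    }
    out[[net$name]] <- m
  }
  out
}

## ---- per-class activation painters (operate on a zero 3D array) -------

paint_boundary <- function(act, spec) {
  grid <- spec$grid
  band <- centred_band(grid[3], 7)
  a0 <- stats::runif(1, 0, 2 * pi)
  arc <- 140 * pi / 180
  for (s in band) {
    rho <- rho_grid(grid, s)
    ang <- slice_angle(grid, s)
    in_arc <- angle_in_arc(ang, a0, arc)
    act[, , s][rho >= 0.91 & rho <= 0.963 & in_arc] <- spec$amp
  }
  act
}

paint_white_matter <- function(act, spec) {
  grid <- spec$grid
  band <- centred_band(grid[3], 7)
  a0 <- stats::runif(1, 0, 2 * pi)
  arc <- 80 * pi / 180
  for (s in band) {
    rho <- rho_grid(grid, s)
    ang <- slice_angle(grid, s)
    in_arc <- angle_in_arc(ang, a0, arc)
    act[, , s][rho >= 0.58 & rho <= 0.75 & in_arc] <- spec$amp
  }
  act
}

paint_vessel <- function(act, spec, anatomy) {
  band <- centred_band(spec$grid[3], 7)
  for (s in band) {
    act[, , s][anatomy$vessels[, , s]] <- spec$amp
  }
  act
}

paint_small_clusters <- function(act, spec, anatomy) {
  grid <- spec$grid
  band <- centred_band(grid[3], 6)
  for (s in band) {
    rho <- rho_grid(grid, s)
    ## candidate block corners on a 5-voxel lattice in the deep core
    ## (inside the white-matter annulus, clear of the vessel zone)
    xs <- seq(4, grid[1] - 6, by = 5)
    ys <- seq(4, grid[2] - 6, by = 5)
    cand <- expand.grid(x = xs, y = ys)
    keep <- rho[cbind(cand$x + 1, cand$y + 1)] < 0.52
    for (ctr in vessel_centres(grid, s, anatomy$n_vessels)) {
      keep <- keep & sqrt((cand$x + 1 - ctr[1])^2 +
                          (cand$y + 1 - ctr[2])^2) > 5
    }
    cand <- cand[keep, , drop = FALSE]
    n_blob <- min(25, nrow(cand))
    pick <- cand[sample.int(nrow(cand), n_blob), , drop = FALSE]
    for (i in seq_len(n_blob)) {
      ## 2x3 blocks: the smallest blob whose interior points pass the
      ## density rule at the default eps / v_min
      act[pick$x[i]:(pick$x[i] + 1), pick$y[i]:(pick$y[i] + 2), s] <- spec$amp
    }
  }
  act
}

paint_rsn <- function(act, spec, net) {
  grid <- spec$grid
  sigma <- max(2, round(0.05 * grid[1])) # matches template disk radius
  for (s in template_band(grid, net)) {
    for (ctr in template_centres(grid, s, net)) {
      act[, , s] <- act[, , s] + gaussian_bump(grid, ctr, sigma, 0.7 * spec$amp)
    }
  }
  act
}

paint_soz <- function(act, spec, centre_xyz, z_threshold = 2) {
  grid <- spec$grid
  band <- seq(max(1, centre_xyz[3] - 2), min(grid[3], centre_xyz[3] + 2))
  for (s in band) {
    taper <- if (s %in% range(band) && length(band) > 3) 0.7 else 1
    low <- disk_mask(grid, centre_xyz[1:2], 6 * taper)
    core <- disk_mask(grid, centre_xyz[1:2], 3 * taper)
    sl <- act[, , s]
    sl[low] <- 1.6 * z_threshold
    sl[core] <- 1.4 * spec$amp
    act[, , s] <- sl
  }
  act
}

centred_band <- function(ns, width) {
  ctr <- round(ns / 2) + sample(-2:2, 1)
  seq(max(1, ctr - floor(width / 2)),
      min(ns, ctr + floor((width - 1) / 2)))
}

slice_angle <- function(grid, s) {
  g <- slice_geometry(grid, s)
  x <- matrix(seq_len(grid[1]), grid[1], grid[2])
  y <- matrix(seq_len(grid[2]), grid[1], grid[2], byrow = TRUE)
  atan2((y - g$cy) / g$ry, (x - g$cx) / g$rx)
}

angle_in_arc <- function(ang, a0, arc) {
  d <- (ang - a0) %% (2 * pi)
  d <= arc
}

gaussian_bump <- function(grid, ctr, sigma, amp) {
  x <- matrix(seq_len(grid[1]), grid[1], grid[2])
  y <- matrix(seq_len(grid[2]), grid[1], grid[2], byrow = TRUE)
  amp * exp(-((x - ctr[1])^2 + (y - ctr[2])^2) / (2 * sigma^2))
}

## seeded SOZ centre in deep gray matter, away from RSN template sites
## and vessels
soz_centre <- function(spec, anatomy, templates) {
  grid <- spec$grid
  t_centres <- do.call(rbind, lapply(seq_len(nrow(RSN_NETWORKS)), function(i) {
    net <- RSN_NETWORKS[i, ]
    s_mid <- round(net$slice_frac * grid[3])
    do.call(rbind, lapply(template_centres(grid, s_mid, net), function(ctr) {
      c(ctr[1], ctr[2], s_mid)
    }))
  }))
  for (attempt in seq_len(60)) {
    s <- round(stats::runif(1, 0.35, 0.65) * grid[3])
    g <- slice_geometry(grid, s)
    rho_s <- stats::runif(1, 0.28, 0.45)
    th <- stats::runif(1, 0, 2 * pi)
    x <- round(g$cx + rho_s * g$rx * cos(th))
    y <- round(g$cy + rho_s * g$ry * sin(th))
    cand <- c(x, y, s)
    d_t <- sqrt((t_centres[, 1] - x)^2 + (t_centres[, 2] - y)^2 +
                (2 * (t_centres[, 3] - s))^2)
    v_ok <- TRUE
    for (ctr in vessel_centres(grid, s, anatomy$n_vessels)) {
      if (sqrt((ctr[1] - x)^2 + (ctr[2] - y)^2) < 10) v_ok <- FALSE
    }
    if (min(d_t) >= 12 && v_ok) return(cand)
  }
  cand
}

## ---- time-course painters ---------------------------------------------

tc_noise <- function(spec) stats::rnorm(spec$t_len)

tc_rsn <- function(spec) {
  f <- stats::runif(1, 0.015, 0.045)
  phi <- stats::runif(1, 0, 2 * pi)
  t <- (seq_len(spec$t_len) - 1) * spec$tr_seconds
  sin(2 * pi * f * t + phi) + stats::rnorm(spec$t_len, 0, 0.2)
}

tc_soz <- function(spec) {
  f <- stats::runif(1, 0.08, 0.105)
  t <- (seq_len(spec$t_len) - 1) * spec$tr_seconds
  centres <- sort(stats::runif(3, 0.08, 0.92)) * spec$t_len
  idx <- seq_len(spec$t_len)
  env <- rowSums(vapply(centres, function(cc) {
    exp(-(idx - cc)^2 / (2 * 6^2))
  }, numeric(spec$t_len)))
  4 * env * sin(2 * pi * f * t) + stats::rnorm(spec$t_len, 0, 0.08)
}

#' Generate one phantom IC
#'
#' Paints the activation pattern and time course of a single IC of the
#' requested class on top of the subject's anatomy background, plus
#' voxel noise at `spec$amp / spec$snr`. RSN maps are built
#' mirror-symmetric (noise field included), matching their bilateral
#' construction. Consumes the current RNG stream; call inside
#' [generate_subject()] or seed explicitly for reproducibility.
#'
#' @param spec A [phantom_spec()].
#' @param anatomy A [generate_anatomy()] result for the same spec.
#' @param templates A [generate_templates()] result for the same grid.
#' @param cls `"noise"`, `"rsn"` or `"soz"`.
#' @param subtype Noise subtype (ignored unless `cls == "noise"`).
#' @return List with `vol` (3D array), `tc` (numeric vector), `truth`
#'   (list: category, subtype, and class-specific extras).
#' @export
generate_ic <- function(spec, anatomy, templates, cls,
                        subtype = "boundary") {
  grid <- spec$grid
  act <- array(0, grid)
  extra <- list()
  if (cls == "noise") {
    stopifnot(subtype %in% NOISE_SUBTYPES)
    act <- switch(subtype,
      boundary = paint_boundary(act, spec),
      white_matter = paint_white_matter(act, spec),
      vessel = paint_vessel(act, spec, anatomy),
      small_clusters = paint_small_clusters(act, spec, anatomy))
    tc <- tc_noise(spec)
  } else if (cls == "rsn") {
    net_i <- sample.int(nrow(RSN_NETWORKS), 1)
    act <- paint_rsn(act, spec, RSN_NETWORKS[net_i, ])
    tc <- tc_rsn(spec)
    extra$network <- RSN_NETWORKS$name[net_i]
  } else if (cls == "soz") {
    ctr <- soz_centre(spec, anatomy, templates)
    act <- paint_soz(act, spec, ctr)
    tc <- tc_soz(spec)
    extra$centre <- ctr
  } else {
    stop("unknown phantom class: ", cls)
  }
  noise_sd <- spec$amp / spec$snr
  vol <- anatomy$background + act +
    array(stats::rnorm(prod(grid), 0, noise_sd), grid)
  if (cls == "rsn") {
    vol <- (vol + vol[rev(seq_len(grid[1])), , , drop = FALSE]) / 2
  }
  truth <- c(list(category = cls,
                  subtype = if (cls == "noise") subtype else "none"),
             extra)
  list(vol = vol, tc = tc, truth = truth)
}

## largest-remainder apportionment of n into proportions p
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(-(raw - base), seq_along(p))
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a phantom subject
#'
#' Draws the per-class IC counts from `class_mix` by deterministic
#' (largest-remainder) rounding, builds every IC, shuffles their order,
#' and returns the decomposition together with ground-truth labels.
#'
#' @param spec A [phantom_spec()].
#' @return List with `dec` (an `"ic_decomposition"`), `truth` (data frame
#'   with 0-based `ic_index`, `category`, `noise_subtype`), `anatomy`,
#'   `templates`.
#' @export
generate_subject <- function(spec) {
  anatomy <- generate_anatomy(spec)
  templates <- generate_templates(spec$grid)
  with_seed(spec$seed + 1L, {
    n_cls <- apportion(spec$n_ics, spec$class_mix)
    n_sub <- apportion(n_cls[1], spec$noise_subtype_mix)
    plan <- data.frame(
      category = c(rep("noise", n_cls[1]), rep("rsn", n_cls[2]),
                   rep("soz", n_cls[3])),
      subtype = c(rep(NOISE_SUBTYPES, times = n_sub),
                  rep("none", n_cls[2] + n_cls[3])),
      stringsAsFactors = FALSE
    )
    plan <- plan[sample.int(nrow(plan)), , drop = FALSE]
    grid <- spec$grid
    maps <- array(0, c(grid, spec$n_ics))
    mix <- matrix(0, spec$t_len, spec$n_ics)
    for (i in seq_len(spec$n_ics)) {
      ic <- generate_ic(spec, anatomy, templates, plan$category[i],
                        plan$subtype[i])
      maps[, , , i] <- ic$vol
      mix[, i] <- ic$tc
    }
    dec <- ic_decomposition(maps, mix, spec$tr_seconds,
                            subject_id = paste0("phantom_seed", spec$seed))
    truth <- data.frame(
      ic_index = seq_len(spec$n_ics) - 1L,
      category = plan$category,
      noise_subtype = plan$subtype,
      stringsAsFactors = FALSE
    )
    list(dec = dec, truth = truth, anatomy = anatomy, templates = templates)
  })
}
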