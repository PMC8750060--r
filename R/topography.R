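#' Default brain-region map (10-20 system)
#'
#' Five scalp regions and their member electrodes. The ear-lobe reference
#' channel A2 belongs to no cortical region and is excluded from region
#' means by default.
#'
#' @return Named list: region name -> character vector of electrode labels.
#' @export
default_region_map <- function() {
  list(
    frontal        = c("Fp1", "Fp2", "F3", "F4"),
    left_temporal  = c("F7", "T3", "T5"),
    central        = c("C3", "C4", "Fz", "Cz", "Pz"),
    right_temporal = c("F8", "T4", "T6"),
    occipital      = c("P3", "P4", "O1", "O2")
  )
}

# Approximate 2-D scalp coordinates (head circle of radius 1, nose up) for
# the supported electrode labels.
electrode_coords <- function() {
  m <- rbind(
    Fp1 = c(-0.28, 0.86), Fp2 = c(0.28, 0.86),
    F7 = c(-0.73, 0.53),  F3 = c(-0.34, 0.43), Fz = c(0, 0.43),
    F4 = c(0.34, 0.43),   F8 = c(0.73, 0.53),
    T3 = c(-0.90, 0),     C3 = c(-0.45, 0),    Cz = c(0, 0),
    C4 = c(0.45, 0),      T4 = c(0.90, 0),
    T5 = c(-0.73, -0.53), P3 = c(-0.34, -0.43), Pz = c(0, -0.43),
    P4 = c(0.34, -0.43),  T6 = c(0.73, -0.53),
    O1 = c(-0.28, -0.86), O2 = c(0.28, -0.86),
    A2 = c(1.08, -0.10)
  )
  colnames(m) <- c("x", "y")
  m
}

#' Per-channel partition entropies of an activation map
#'
#' Each channel's activation matrix is flattened to a 1-D series and scored
#' with [partition_entropy()]; channels are independent of one another.
#'
#' @param am An `activation_map`.
#' @param ... Passed to [partition_entropy()] (AP options).
#' @return Named numeric vector of entropies (bits), one per channel.
#' @export
channel_entropies <- function(am, ...) {
  stopifnot(inherits(am, "activation_map"))
  vapply(am$per_channel, function(m) partition_entropy(as.vector(m), ...),
         numeric(1))
}

#' Average entropy per brain region
#'
#' Arithmetic mean of the member channels' entropies for each region of the
#' map. Electrodes missing from `per_channel_entropy` are excluded with a
#' warning; a region left empty yields `NA` with a warning.
#'
#' @param per_channel_entropy Named numeric vector (names = channel labels).
#' @param region_map Named list, region -> electrodes; default
#'   [default_region_map()].
#' @return Named numeric vector of per-region mean entropies (bits).
#' @export
region_means <- function(per_channel_entropy, region_map = default_region_map()) {
  if (is.null(names(per_channel_entropy))) {
    stop("`per_channel_entropy` must be named by channel label", call. = FALSE)
  }
  out <- vapply(names(region_map), function(rg) {
    members <- region_map[[rg]]
    present <- members %in% names(per_channel_entropy)
    if (any(!present)) {
      warning(sprintf("region %s: electrode(s) %s not among channels; excluded",
                      rg, paste(members[!present], collapse = ", ")),
              call. = FALSE)
    }
    members <- members[present]
    if (length(members) == 0L) {
      warning(sprintf("region %s has no member channels; mean undefined", rg),
              call. = FALSE)
      return(NA_real_)
    }
    mean(per_channel_entropy[members])
  }, numeric(1))
  out
}

#' Assemble an entropy topography object
#'
#' @param per_channel_entropy Named numeric vector of channel entropies.
#' @param region_map Region -> electrode list; default [default_region_map()].
#' @return An object of class `entropy_topography` with per-channel and
#'   per-region entropies.
#' @export
entropy_topography <- function(per_channel_entropy,
                               region_map = default_region_map()) {
  structure(
    list(
      per_channel_entropy = per_channel_entropy,
      per_region_entropy = region_means(per_channel_entropy, region_map),
      region_map = region_map
    ),
    class = "entropy_topography"
  )
}

#' @export
print.entropy_topography <- function(x, ...) {
  cat("<entropy_topography>\n  per-region entropy (bits):\n")
  for (rg in names(x$per_region_entropy)) {
    cat(sprintf("    %-14s %.4f\n", rg, x$per_region_entropy[rg]))
  }
  invisible(x)
}

#' Render a scalp topography image
#'
#' Channel level: inverse-distance-weighted interpolation of the per-channel
#' entropies over the head disc. Region level: piecewise-constant map, each
#' location taking the region mean of its nearest region electrode. Output
#' is a PNG; fully deterministic for fixed input.
#'
#' @param topo An [entropy_topography()].
#' @param level `"channel"` or `"region"`.
#' @param out_path Output PNG path.
#' @param grid_n Interpolation grid resolution per axis (default 120).
#' @return `out_path`, invisibly.
#' @export
render_topography <- function(topo, level = c("channel", "region"), out_path,
                              grid_n = 120L) {
  level <- match.arg(level)
  coords <- electrode_coords()
  if (level == "channel") {
    vals <- topo$per_channel_entropy
  } else {
    per_region <- topo$per_region_entropy
    labs <- unlist(topo$region_map, use.names = FALSE)
    vals <- stats::setNames(
      rep(per_region, lengths(topo$region_map)), labs
    )
    vals <- vals[!is.na(vals)]
  }
  unknown <- setdiff(names(vals), rownames(coords))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown electrode label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  xy <- coords[names(vals), , drop = FALSE]
  gx <- seq(-1.15, 1.15, length.out = grid_n)
  gy <- seq(-1.15, 1.15, length.out = grid_n)
  grid <- expand.grid(x = gx, y = gy)
  z <- if (level == "channel") {
    # inverse-distance weighting, power 2
    apply(grid, 1, function(p) {
      d2 <- (xy[, "x"] - p[1])^2 + (xy[, "y"] - p[2])^2
      if (any(d2 < 1e-12)) return(vals[which.min(d2)])
      w <- 1 / d2
      sum(w * vals) / sum(w)
    })
  } else {
    apply(grid, 1, function(p) {
      d2 <- (xy[, "x"] - p[1])^2 + (xy[, "y"] - p[2])^2
      vals[which.min(d2)]
    })
  }
  z[grid$x^2 + grid$y^2 > 1.12^2] <- NA
  zmat <- matrix(z, nrow = grid_n)
  grDevices::png(out_path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::image(gx, gy, zmat, col = grDevices::hcl.colors(64, "viridis"),
                  asp = 1, axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("Partition entropy (bits), %s level", level))
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), lwd = 2)
  graphics::lines(c(-0.1, 0, 0.1), c(0.995, 1.08, 0.995), lwd = 2) # nose
  graphics::points(xy[, "x"], xy[, "y"], pch = 21, bg = "white")
  graphics::text(xy[, "x"], xy[, "y"], labels = names(vals), pos = 3,
                 cex = 0.7)
  invisible(out_path)
}

#' Write interpretation outputs to a directory
#'
#' Runs [activation_maximization()], [channel_entropies()] and
#' [region_means()] on a trained model and writes per-channel and per-region
#' CSVs plus channel- and region-level topography PNGs.
#'
#' @param model A trained `fccnn_model`.
#' @param out_dir Output directory (created if needed).
#' @param cfg An [am_config()].
#' @param region_map Region map; default [default_region_map()].
#' @param channel_labels Optional channel labels for the model input rows.
#' @return The [entropy_topography()], invisibly.
#' @export
interpret_model <- function(model, out_dir, cfg = am_config(),
                            region_map = default_region_map(),
                            channel_labels = default_montage()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  attr(model, "channel_labels") <- channel_labels[seq_len(model$input_shape[1])]
  am <- activation_maximization(model, cfg)
  ent <- channel_entropies(am)
  topo <- entropy_topography(ent, region_map)
  data.table::fwrite(
    data.table::data.table(channel = names(ent), entropy_bits = unname(ent)),
    file.path(out_dir, "channel_entropy.csv")
  )
  data.table::fwrite(
    data.table::data.table(region = names(topo$per_region_entropy),
                           entropy_bits = unname(topo$per_region_entropy)),
    file.path(out_dir, "region_entropy.csv")
  )
  render_topography(topo, "channel", file.path(out_dir, "topography_channel.png"))
  render_topography(topo, "region", file.path(out_dir, "topography_region.png"))
  invisible(topo)
}
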