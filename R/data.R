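# Readers/writers, depth-frame projection, resampling, augmentation and
# session-level splitting. Clouds on disk are whitespace-separated "x y z"
# text files, one point per line; a manifest CSV (file,label,session_id)
# maps files to individuals and recording sessions.

#' Read a point cloud from a whitespace-separated text file
#'
#' Each line holds at least three numeric fields (x, y, z); extra trailing
#' columns (e.g. colors) are ignored with a warning. Malformed lines raise a
#' parse error naming the line number.
#'
#' @param path file path.
#' @return N x 3 numeric matrix.
#' @export
read_cloud_txt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty point cloud file: %s", path)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(toks)
  if (any(nf < 3L))
    stopf("malformed line %d in %s: expected at least 3 numeric fields",
          which(nf < 3L)[1L], path)
  if (any(nf > 3L))
    warnf("%s: extra trailing columns ignored (first offending line %d)",
          path, which(nf > 3L)[1L])
  vals <- suppressWarnings(
    vapply(toks, function(t) as.numeric(t[1:3]), numeric(3)))
  bad <- which(colSums(is.na(vals)) > 0)
  if (length(bad))
    stopf("malformed line %d in %s: non-numeric coordinate", bad[1L], path)
  cloud <- t(vals)
  validate_cloud(cloud)
  cloud
}

#' Write a point cloud as whitespace-separated text
#'
#' @param cloud N x 3 matrix.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cloud_txt <- function(cloud, path) {
  validate_cloud(cloud)
  utils::write.table(format(cloud, digits = 9, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY file's vertex coordinates
#'
#' Minimal reader for ASCII PLY files with x/y/z vertex properties.
#'
#' @param path file path.
#' @return N x 3 numeric matrix.
#' @export
read_cloud_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1L]) != "ply") stopf("not a PLY file: %s", path)
  endh <- which(trimws(lines) == "end_header")[1L]
  if (is.na(endh)) stopf("PLY header without end_header: %s", path)
  header <- lines[seq_len(endh)]
  fmt <- grep("^format", trimws(header), value = TRUE)
  if (!length(fmt) || !grepl("ascii", fmt[1L]))
    stopf("only ASCII PLY is supported: %s", path)
  vline <- grep("^element vertex", trimws(header), value = TRUE)
  if (!length(vline)) stopf("PLY file without vertex element: %s", path)
  nv <- as.integer(strsplit(trimws(vline[1L]), "[[:space:]]+")[[1L]][3L])
  props <- grep("^property", trimws(header), value = TRUE)
  pnames <- vapply(strsplit(props, "[[:space:]]+"),
                   function(t) t[length(t)], character(1))
  ix <- match(c("x", "y", "z"), pnames)
  if (any(is.na(ix))) stopf("PLY vertex element lacks x/y/z properties: %s", path)
  body <- lines[(endh + 1L):(endh + nv)]
  toks <- strsplit(trimws(body), "[[:space:]]+")
  cloud <- t(vapply(toks, function(t) as.numeric(t[ix]), numeric(3)))
  validate_cloud(cloud)
  cloud
}

#' Write a point cloud as ASCII PLY
#'
#' @inheritParams write_cloud_txt
#' @export
write_cloud_ply <- function(cloud, path) {
  validate_cloud(cloud)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(cloud)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  utils::write.table(format(cloud, digits = 9, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pinhole camera intrinsics
#'
#' Convention: X right, Y down, Z forward (optical axis); pixel indices are
#' 0-based; depth is in meters.
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy) {
  if (fx <= 0 || fy <= 0) stopf("focal lengths must be positive")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy),
            class = "camera_intrinsics")
}

#' Project a depth frame into a 3-D point cloud
#'
#' For pixel (u, v) with depth Z: `X = (u - cx) * Z / fx`,
#' `Y = (v - cy) * Z / fy`. The depth array is indexed `depth[v + 1, u + 1]`
#' (row = image row v, 0-based). Only pixels with `valid_mask` TRUE and
#' positive depth are emitted.
#'
#' @param depth H x W matrix of depth values in meters.
#' @param intr a [camera_intrinsics()].
#' @param valid_mask optional logical H x W matrix; defaults to `depth > 0`.
#' @return N x 3 point matrix in camera coordinates.
#' @export
depth_to_cloud <- function(depth, intr, valid_mask = NULL) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  if (any(depth < 0, na.rm = TRUE)) stopf("depth values must be non-negative")
  if (is.null(valid_mask)) valid_mask <- depth > 0
  valid_mask <- valid_mask & is.finite(depth) & depth > 0
  if (!any(valid_mask)) stopf("no valid pixels in the depth frame")
  h <- nrow(depth); w <- ncol(depth)
  vv <- matrix(rep(0:(h - 1L), times = w), h, w)
  uu <- matrix(rep(0:(w - 1L), each = h), h, w)
  z <- depth[valid_mask]
  u <- uu[valid_mask]
  v <- vv[valid_mask]
  out <- cbind((u - intr$cx) * z / intr$fx,
               (v - intr$cy) * z / intr$fy,
               z)
  dimnames(out) <- NULL
  out
}

#' Render a point cloud back into a depth frame
#'
#' Inverse of [depth_to_cloud()] for synthetic round-trip checks: each point
#' is projected to its pixel; when several points fall on one pixel the
#' nearest survives.
#'
#' @param cloud N x 3 point matrix in camera coordinates (Z > 0).
#' @param intr a [camera_intrinsics()].
#' @param width,height frame size in pixels.
#' @return H x W depth matrix with 0 at empty pixels.
#' @export
cloud_to_depth <- function(cloud, intr, width, height) {
  validate_cloud(cloud)
  if (any(cloud[, 3] <= 0)) stopf("all points must have positive depth Z")
  u <- round(cloud[, 1] * intr$fx / cloud[, 3] + intr$cx)
  v <- round(cloud[, 2] * intr$fy / cloud[, 3] + intr$cy)
  keep <- u >= 0 & u < width & v >= 0 & v < height
  depth <- matrix(0, height, width)
  ord <- order(cloud[, 3], decreasing = TRUE) # nearest written last
  for (i in ord[keep[ord]]) depth[v[i] + 1L, u[i] + 1L] <- cloud[i, 3]
  depth
}

#' Resample a cloud to a fixed point count
#'
#' Uniform sampling without replacement when the cloud has at least `n`
#' points, with replacement when it has fewer (so the output is always a
#' sub-multiset of the input).
#'
#' @param cloud N x 3 point matrix.
#' @param n target point count (default 2048).
#' @param seed optional seed for reproducibility.
#' @return n x 3 matrix.
#' @export
resample_fixed <- function(cloud, n = 2048, seed = NULL) {
  validate_cloud(cloud)
  n <- as.integer(n)
  pick <- function() sample.int(nrow(cloud), n, replace = nrow(cloud) < n)
  idx <- if (is.null(seed)) pick() else with_seed_preserved(seed, pick())
  cloud[idx, , drop = FALSE]
}

#' Training-time augmentation
#'
#' One isotropic scale factor drawn uniformly from [0.8, 1.2], one per-axis
#' translation drawn uniformly from [-0.1, 0.1]^3, then a random shuffle of
#' the point order, in that fixed order. Rotation is never applied: overhead
#' depth cameras keep dorsal clouds gravity-aligned.
#'
#' @param cloud normalized N x 3 point matrix.
#' @param seed optional seed.
#' @param scale_range,translate_range augmentation bounds.
#' @return augmented N x 3 matrix.
#' @export
augment_cloud <- function(cloud, seed = NULL, scale_range = c(0.8, 1.2),
                          translate_range = c(-0.1, 0.1)) {
  validate_cloud(cloud)
  run <- function() {
    s <- stats::runif(1, scale_range[1], scale_range[2])
    tr <- stats::runif(3, translate_range[1], translate_range[2])
    out <- cloud * s
    out <- sweep(out, 2L, tr, "+")
    out[sample.int(nrow(out)), , drop = FALSE]
  }
  if (is.null(seed)) run() else with_seed_preserved(seed, run())
}

#' A labelled sample
#'
#' @param cloud N x 3 point matrix.
#' @param label integer class id in `1..num_classes`.
#' @param session_id non-empty string identifying the recording session the
#'   frame came from (the unit of train/test splitting).
#' @export
pc_sample <- function(cloud, label, session_id) {
  validate_cloud(cloud)
  label <- as.integer(label)
  if (is.na(label) || label < 1L) stopf("`label` must be a positive integer")
  session_id <- as.character(session_id)
  if (!nzchar(session_id)) stopf("`session_id` must be non-empty")
  structure(list(cloud = cloud, label = label, session_id = session_id),
            class = "pc_sample")
}

sample_labels <- function(samples) vapply(samples, `[[`, integer(1), "label")
sample_sessions <- function(samples) vapply(samples, `[[`, character(1), "session_id")

#' Session-level train/test split
#'
#' Assigns whole recording sessions (never individual frames) to one side,
#' so that no frames from the same continuous recording appear in both
#' subsets - the temporal-leakage guard of a video-level split. Sessions
#' are ordered canonically before seeded shuffling, so the split is
#' invariant to the input sample order. Per class, both sides are non-empty
#' whenever the class has at least two sessions; a single-session class goes
#' wholly to the training side with a warning.
#'
#' @param samples list of [pc_sample()] objects.
#' @param train_fraction target training fraction of sessions per class.
#' @param seed seed controlling the session shuffle.
#' @return list with elements `train` and `test` (lists of samples) and
#'   `train_sessions` / `test_sessions` (character vectors).
#' @export
video_level_split <- function(samples, train_fraction = 0.8, seed = 42) {
  if (!length(samples)) stopf("`samples` is empty")
  labels <- sample_labels(samples)
  sessions <- sample_sessions(samples)
  train_sessions <- character(0)
  test_sessions <- character(0)
  for (cl in sort(unique(labels))) {
    ses <- sort(unique(sessions[labels == cl]))
    if (length(ses) < 2L) {
      warnf("class %d has a single session; it goes to the training set and is absent from the test set", cl)
      train_sessions <- c(train_sessions, ses)
      next
    }
    ses <- with_seed_preserved(derive_seed(seed, cl), sample(ses))
    ntr <- max(1L, min(length(ses) - 1L, round(train_fraction * length(ses))))
    train_sessions <- c(train_sessions, ses[seq_len(ntr)])
    test_sessions <- c(test_sessions, ses[-seq_len(ntr)])
  }
  in_train <- sessions %in% train_sessions
  list(train = samples[in_train],
       test = samples[!in_train],
       train_sessions = sort(train_sessions),
       test_sessions = sort(test_sessions))
}

#' Write a dataset directory (cloud text files plus manifest CSV)
#'
#' @param samples list of [pc_sample()] objects.
#' @param dir destination directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("sample_%05d.txt", seq_along(samples))
  for (i in seq_along(samples))
    write_cloud_txt(samples[[i]]$cloud, file.path(dir, files[i]))
  manifest <- data.frame(file = files,
                         label = sample_labels(samples),
                         session_id = sample_sessions(samples),
                         stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return list of [pc_sample()] objects.
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i)
    pc_sample(read_cloud_txt(file.path(dir, manifest$file[i])),
              manifest$label[i], manifest$session_id[i]))
}
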