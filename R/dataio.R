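#' Read and write frames and masks
#'
#' Frames are 8-bit grayscale PNG images with intensities 0-255; gold masks
#' are PNGs using values 0/255 and are coerced to 0/1 labels on reading (any
#' nonzero pixel becomes foreground).  Images are held in R as plain numeric
#' matrices indexed `[row, column]` with row 1 at the image top.
#'
#' @param path File path.
#' @return `read_frame()` an integer matrix 0-255; `read_mask()` an integer
#'   matrix 0/1.
#' @name frame_io
NULL

#' @rdname frame_io
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop_thinseg("file not found: ", path)
  px <- png::readPNG(path)
  if (length(dim(px)) != 2L) {
    stop_thinseg("not an 8-bit grayscale PNG (multi-channel image): ", path)
  }
  matrix(as.integer(round(px * 255)), nrow(px), ncol(px))
}

#' @rdname frame_io
#' @param frame Integer matrix with values 0-255.
#' @export
write_frame <- function(frame, path) {
  if (any(frame < 0 | frame > 255)) {
    stop_thinseg("frame intensities must lie in [0, 255]")
  }
  png::writePNG(frame / 255, path)
  invisible(path)
}

#' @rdname frame_io
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop_thinseg("file not found: ", path)
  px <- png::readPNG(path)
  if (length(dim(px)) != 2L) {
    stop_thinseg("not an 8-bit grayscale PNG (multi-channel image): ", path)
  }
  matrix(as.integer(px != 0), nrow(px), ncol(px))
}

#' @rdname frame_io
#' @param mask Integer matrix with values 0/1 (or anything nonzero for
#'   foreground).
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' Read and validate a dataset manifest
#'
#' The manifest is a CSV with columns `frame_path`, `mask_path`,
#' `patient_id`, `sequence_id`, `frame_index`, `stage`.
#'
#' @param path Path to `manifest.csv`.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  validate_manifest(m, check_files = FALSE)
  m
}

#' @rdname read_manifest
#' @param manifest Manifest tibble.
#' @param check_files Also open every referenced file and check that frame
#'   and mask shapes match (slower).
#' @export
validate_manifest <- function(manifest, check_files = TRUE) {
  needed <- c("frame_path", "mask_path", "patient_id", "sequence_id",
              "frame_index", "stage")
  missing_cols <- setdiff(needed, names(manifest))
  if (length(missing_cols)) {
    stop_thinseg("manifest lacks column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  key <- paste(manifest$patient_id, manifest$sequence_id,
               manifest$frame_index)
  if (anyDuplicated(key)) {
    stop_thinseg("(patient_id, sequence_id, frame_index) must be unique")
  }
  if (check_files) {
    for (i in seq_len(nrow(manifest))) {
      fr <- read_frame(manifest$frame_path[i])
      mk <- read_mask(manifest$mask_path[i])
      if (!identical(dim(fr), dim(mk))) {
        stop_thinseg(sprintf(
          "frame/mask shape mismatch: %s is %s but %s is %s",
          manifest$frame_path[i], paste(dim(fr), collapse = "x"),
          manifest$mask_path[i], paste(dim(mk), collapse = "x")
        ))
      }
    }
  }
  invisible(manifest)
}

#' Patient-wise train/test split
#'
#' Partitions *patients* (never frames) into a training and a test side so
#' that no patient contributes frames to both, avoiding leakage of
#' patient-specific appearance into the test set.  Among all patient
#' subsets, the test side is the one whose total frame count is closest to
#' `test_fraction` of all frames; ties are broken by fewer test patients,
#' then by lexicographic patient ids.  For up to 16 patients the optimum is
#' found by exhaustive search (deterministic; the seed is unused); beyond
#' that a seeded randomized search is used.
#'
#' @param manifest Manifest tibble.
#' @param test_fraction Target fraction of frames on the test side.
#' @param seed Integer seed (only consulted for > 16 patients).
#' @return An object of class `"split_spec"`: a list with `train_patients`,
#'   `test_patients`, `n_train_frames`, `n_test_frames`, `test_fraction`
#'   (achieved), and `seed`.
#' @export
patient_split <- function(manifest, test_fraction = 0.2, seed = 1L) {
  exhaustive_limit <- 16L
  counts <- table(manifest$patient_id)
  ids <- sort(names(counts))
  nfr <- as.numeric(counts[ids])
  np <- length(ids)
  if (np < 2) {
    stop_thinseg("patient-wise split needs >= 2 patients; with a single ",
                 "patient train/test leakage is unavoidable")
  }
  total <- sum(nfr)
  target <- test_fraction * total

  best <- NULL
  score <- function(sel) {
    ntest <- sum(nfr[sel])
    c(abs(ntest - target), sum(sel))
  }
  consider <- function(sel) {
    s <- score(sel)
    if (is.null(best) ||
        s[1] < best$s[1] - 1e-9 ||
        (abs(s[1] - best$s[1]) < 1e-9 && s[2] < best$s[2]) ||
        (abs(s[1] - best$s[1]) < 1e-9 && s[2] == best$s[2] &&
           paste(ids[sel], collapse = ",") <
             paste(ids[best$sel], collapse = ","))) {
      best <<- list(sel = sel, s = s)
    }
  }
  if (np <= exhaustive_limit) {
    for (code in 1:(2^np - 2)) {
      sel <- as.logical(bitwAnd(bitwShiftR(code, seq_len(np) - 1L), 1L))
      consider(sel)
    }
  } else {
    local_seed(seed, {
      for (iter in seq_len(20000L)) {
        k <- sample(seq_len(np - 1L), 1L)
        sel <- seq_len(np) %in% sample(np, k)
        consider(sel)
      }
    })
  }
  sel <- best$sel
  structure(
    list(
      train_patients = ids[!sel],
      test_patients = ids[sel],
      n_train_frames = as.integer(sum(nfr[!sel])),
      n_test_frames = as.integer(sum(nfr[sel])),
      test_fraction = sum(nfr[sel]) / total,
      seed = as.integer(seed)
    ),
    class = "split_spec"
  )
}

#' @export
print.split_spec <- function(x, ...) {
  cat("Patient-wise split:", length(x$train_patients), "train /",
      length(x$test_patients), "test patients;",
      x$n_train_frames, "train /", x$n_test_frames, "test frames (",
      sprintf("%.1f%%", 100 * x$test_fraction), "test )\n")
  invisible(x)
}

#' Nested training subsets
#'
#' Draws training subsets of increasing sizes such that each subset is
#' contained in all larger ones: the largest is sampled uniformly from all
#' training rows, and each smaller one uniformly from the next larger.
#'
#' @param train_rows Tibble of training manifest rows.
#' @param sizes Strictly increasing subset sizes; the largest must not
#'   exceed `nrow(train_rows)`.
#' @param seed Integer seed; the subsets are deterministic given it.
#' @return A named list of tibbles (`"n75"`, `"n150"`, ... for
#'   `sizes = c(75, 150, ...)`), smallest first.
#' @export
nested_subsets <- function(train_rows, sizes = c(75L, 150L, 300L, 600L),
                           seed = 1L) {
  sizes <- as.integer(sizes)
  if (any(diff(sizes) <= 0)) {
    stop_thinseg("sizes must be strictly increasing")
  }
  if (max(sizes) > nrow(train_rows)) {
    stop_thinseg("largest subset size (", max(sizes),
                 ") exceeds the number of training rows (",
                 nrow(train_rows), ")")
  }
  local_seed(seed, {
    out <- vector("list", length(sizes))
    names(out) <- paste0("n", sizes)
    current <- train_rows
    for (j in rev(seq_along(sizes))) {
      idx <- sort(sample(nrow(current), sizes[j]))
      current <- current[idx, , drop = FALSE]
      out[[j]] <- current
    }
    out
  })
}
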