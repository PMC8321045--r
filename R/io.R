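# Parcel time-series containers and tabular input/output.
#
# A parcel dataset is a tibble with one row per field parcel:
#   parcel_id  character, unique
#   region     character region code (e.g. "FRH01")
#   label      integer class index in [0, n_classes)
#   series     list-column of T_raw x B reflectance matrices
# plus, after standardize_series(), a `mask` list-column of length-T 0/1
# vectors marking observed vs padded steps. Dataset-level facts (class count,
# band count, class names, scale divisor) travel in the "ts_meta" attribute.

#' Construct a parcel time-series tibble
#'
#' Assembles the package's central data structure: one row per parcel with a
#' list-column of T x B reflectance matrices, validated against the declared
#' class and band counts.
#'
#' @param parcel_id Character vector of unique parcel identifiers.
#' @param region Character vector of region codes.
#' @param label Integer vector of 0-based class indices.
#' @param series List of numeric matrices, one per parcel, each with one row
#'   per observation date and one column per spectral band.
#' @param n_classes Declared number of classes; defaults to `max(label) + 1`.
#' @param class_names Optional character vector of length `n_classes`.
#' @param scale_divisor Divisor already applied to raw digital numbers
#'   (recorded for provenance; values are stored post-division).
#' @return A tibble of class `parcel_tbl` carrying a `ts_meta` attribute.
#' @export
parcel_tibble <- function(parcel_id, region, label, series,
                          n_classes = NULL, class_names = NULL,
                          scale_divisor = 1) {
  label <- as.integer(label)
  if (is.null(n_classes)) n_classes <- max(label) + 1L
  n_classes <- as.integer(n_classes)
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(n_classes) - 1L)
  df <- tibble(
    parcel_id = as.character(parcel_id),
    region = as.character(region),
    label = label,
    series = series
  )
  meta <- list(
    n_classes = n_classes,
    n_bands = ncol(series[[1]]),
    class_names = class_names,
    scale_divisor = scale_divisor,
    t_steps = NA_integer_
  )
  attr(df, "ts_meta") <- meta
  class(df) <- c("parcel_tbl", class(df))
  validate_parcels(df)
}

#' Validate a parcel dataset against its declared structure
#'
#' Checks the container invariants: a constant band count across parcels,
#' finite reflectances, and labels inside `[0, n_classes)`.
#'
#' @param df A parcel tibble.
#' @param n_classes Declared class count; defaults to the dataset metadata.
#' @return `df`, invisibly, when all checks pass.
#' @export
validate_parcels <- function(df, n_classes = NULL) {
  meta <- parcel_meta(df)
  if (is.null(n_classes)) n_classes <- meta$n_classes
  need <- c("parcel_id", "region", "label", "series")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("parcel data is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tripletlstm_format_error")
  }
  bands <- vapply(df$series, ncol, integer(1))
  if (length(unique(bands)) > 1) {
    abort("all parcels must have the same number of spectral bands",
          class = "tripletlstm_format_error")
  }
  if (!is.null(meta$n_bands) && bands[1] != meta$n_bands) {
    abort(sprintf("series have %d bands but metadata declares %d",
                  bands[1], meta$n_bands),
          class = "tripletlstm_format_error")
  }
  if (any(vapply(df$series, function(m) any(!is.finite(m)), logical(1)))) {
    abort("reflectance values must all be finite",
          class = "tripletlstm_format_error")
  }
  bad <- df$label < 0L | df$label >= n_classes
  if (any(bad)) {
    abort(sprintf("label(s) outside [0, %d) at row(s) %s", n_classes,
                  paste(head(which(bad), 5), collapse = ", ")),
          class = "tripletlstm_format_error")
  }
  invisible(df)
}

#' Read or replace dataset-level metadata
#'
#' @param df A parcel tibble.
#' @return A list with elements `n_classes`, `n_bands`, `class_names`,
#'   `scale_divisor` and `t_steps` (NA before standardization). Missing
#'   entries are inferred from the data.
#' @export
parcel_meta <- function(df) {
  meta <- attr(df, "ts_meta")
  if (is.null(meta)) meta <- list()
  if (is.null(meta$n_classes) && nrow(df) > 0)
    meta$n_classes <- max(df$label) + 1L
  if (is.null(meta$n_bands) && nrow(df) > 0)
    meta$n_bands <- ncol(df$series[[1]])
  if (is.null(meta$class_names) && !is.null(meta$n_classes))
    meta$class_names <- paste0("class_", seq_len(meta$n_classes) - 1L)
  if (is.null(meta$scale_divisor)) meta$scale_divisor <- 1
  if (is.null(meta$t_steps)) meta$t_steps <- NA_integer_
  meta
}

`parcel_meta<-` <- function(df, value) {
  attr(df, "ts_meta") <- value
  df
}

band_col_names <- function(t_steps, n_bands) {
  # wide layout: timestep-major, t001_b01 ... band order = file column order
  as.vector(t(outer(seq_len(t_steps), seq_len(n_bands),
                    function(t, b) sprintf("t%03d_b%02d", t, b))))
}

#' Write a parcel dataset to a wide tabular file
#'
#' One row per parcel; reflectances in columns `t{ttt}_b{bb}` (timestep-major),
#' padded with `NA` beyond each parcel's own sequence length. A JSON sidecar
#' (`<path>.meta.json`) records class count, band count, class names and the
#' scale divisor so that [read_parcels()] round-trips all fields.
#'
#' @param df A parcel tibble.
#' @param path Output file; `.csv` or `.parquet` (the latter needs the arrow
#'   package).
#' @param sidecar Whether to write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_parcels <- function(df, path, sidecar = TRUE) {
  validate_parcels(df)
  meta <- parcel_meta(df)
  lens <- vapply(df$series, nrow, integer(1))
  t_max <- max(lens)
  nb <- meta$n_bands
  wide <- matrix(NA_real_, nrow(df), t_max * nb)
  for (i in seq_len(nrow(df))) {
    wide[i, seq_len(lens[i] * nb)] <- as.vector(t(df$series[[i]]))
  }
  colnames(wide) <- band_col_names(t_max, nb)
  out <- dplyr::bind_cols(
    tibble(parcel_id = df$parcel_id, region = df$region,
           label = df$label, length = lens),
    as_tibble(wide)
  )
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      abort("the arrow package is required to write parquet files")
    arrow::write_parquet(out, path)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  if (sidecar) {
    jsonlite::write_json(
      list(format = "tripletlstm-parcels", version = 1L,
           n_classes = meta$n_classes, n_bands = nb,
           class_names = meta$class_names,
           scale_divisor = meta$scale_divisor),
      paste0(path, ".meta.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a parcel dataset from a wide tabular file
#'
#' Inverse of [write_parcels()]. Band order is taken from the file's column
#' order; values are divided by `scale_divisor` (declared, never inferred —
#' Sentinel-2 L1C digital numbers use 10000, already-scaled data 1).
#'
#' @param path `.csv` or `.parquet` file in the wide layout of
#'   [write_parcels()].
#' @param sidecar Path of the JSON sidecar; defaults to `<path>.meta.json`
#'   when that file exists.
#' @param scale_divisor Overrides the sidecar's divisor (default: sidecar
#'   value, else 1).
#' @return A parcel tibble.
#' @export
read_parcels <- function(path, sidecar = NULL, scale_divisor = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "tripletlstm_format_error")
  }
  if (is.null(sidecar) && file.exists(paste0(path, ".meta.json"))) {
    sidecar <- paste0(path, ".meta.json")
  }
  side <- if (!is.null(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(scale_divisor)) {
    scale_divisor <- if (!is.null(side$scale_divisor)) side$scale_divisor else 1
  }

  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      abort("the arrow package is required to read parquet files")
    raw <- as_tibble(arrow::read_parquet(path))
  } else {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  }
  for (col in c("parcel_id", "region", "label", "length")) {
    if (!col %in% names(raw)) {
      abort(sprintf("input file is missing required column '%s'", col),
            class = "tripletlstm_format_error")
    }
  }
  vcols <- grep("^t\\d+_b\\d+$", names(raw), value = TRUE)
  if (length(vcols) == 0) {
    abort("input file has no reflectance columns (expected t{ttt}_b{bb})",
          class = "tripletlstm_format_error")
  }
  n_bands <- length(unique(sub("^t\\d+_", "", vcols)))
  vals <- matrix(NA_real_, nrow(raw), length(vcols))
  for (j in seq_along(vcols)) {
    x <- raw[[vcols[j]]]
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric reflectance in column '%s' at row %d",
                    vcols[j], bad[1]),
            class = "tripletlstm_parse_error")
    }
    vals[, j] <- num
  }
  lens <- as.integer(raw$length)
  series <- lapply(seq_len(nrow(raw)), function(i) {
    m <- matrix(vals[i, seq_len(lens[i] * n_bands)], nrow = lens[i],
                ncol = n_bands, byrow = TRUE)
    m / scale_divisor
  })
  parcel_tibble(
    parcel_id = raw$parcel_id,
    region = raw$region,
    label = as.integer(raw$label),
    series = series,
    n_classes = if (!is.null(side$n_classes)) side$n_classes else NULL,
    class_names = if (!is.null(side$class_names)) side$class_names else NULL,
    scale_divisor = scale_divisor
  )
}

even_subsample_idx <- function(t_raw, t_steps) {
  # stride decimation: floor(j * T_raw / T), j = 0..T-1 (0-based), so a
  # 90-step sequence reduced to 45 keeps indices 0, 2, ..., 88
  floor((seq_len(t_steps) - 1) * t_raw / t_steps) + 1L
}

#' Standardize sequences to a fixed temporal length
#'
#' Every series becomes exactly `t_steps` rows: longer sequences are reduced
#' by evenly spaced index subsampling (stride `T_raw / T`, first observation
#' always kept); shorter ones are right-padded with zero rows. A `mask`
#' list-column marks observed (1) vs padded (0) steps. The default encoder
#' feeds padded steps as zeros and does not consume the mask. The operation
#' is deterministic and idempotent on already-length-`t_steps` data.
#'
#' @param df A parcel tibble.
#' @param t_steps Target sequence length (default 45).
#' @return The tibble with standardized `series` and a `mask` column.
#' @export
standardize_series <- function(df, t_steps = 45L) {
  t_steps <- as.integer(t_steps)
  if (t_steps < 1) abort("t_steps must be >= 1")
  meta <- parcel_meta(df)
  nb <- meta$n_bands
  out <- df
  out$mask <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    m <- df$series[[i]]
    t_raw <- nrow(m)
    if (t_raw < 1) abort(sprintf("empty series for parcel %s", df$parcel_id[i]))
    if (t_raw >= t_steps) {
      out$series[[i]] <- m[even_subsample_idx(t_raw, t_steps), , drop = FALSE]
      out$mask[[i]] <- rep(1L, t_steps)
    } else {
      pad <- matrix(0, t_steps - t_raw, nb)
      out$series[[i]] <- rbind(m, pad)
      out$mask[[i]] <- c(rep(1L, t_raw), rep(0L, t_steps - t_raw))
    }
  }
  meta$t_steps <- t_steps
  parcel_meta(out) <- meta
  out
}

#' Partition parcels into train/validation/test by region
#'
#' Applies a region-to-split map (the reference split trains on FRH01 and
#' FRH02, validates on FRH03 and tests on FRH04) and records it in a `split`
#' column. The mapping must cover every region present.
#'
#' @param df A parcel tibble.
#' @param rule Named character vector mapping region codes to
#'   `"train"`, `"validation"` or `"test"`.
#' @param quiet Suppress the per-split count message.
#' @return The tibble with an added `split` factor column.
#' @export
split_by_region <- function(df, rule, quiet = FALSE) {
  if (is.null(names(rule)) || any(names(rule) == "")) {
    abort("`rule` must be a named vector: region -> split")
  }
  bad_target <- setdiff(unique(rule), c("train", "validation", "test"))
  if (length(bad_target) > 0) {
    abort(paste0("unknown split target(s): ", paste(bad_target, collapse = ", ")))
  }
  unknown <- setdiff(unique(df$region), names(rule))
  if (length(unknown) > 0) {
    abort(paste0("region(s) not covered by the split rule: ",
                 paste(unknown, collapse = ", ")),
          class = "tripletlstm_split_error")
  }
  out <- df
  out$split <- factor(unname(rule[df$region]),
                      levels = c("train", "validation", "test"))
  if (!quiet) {
    counts <- table(out$split)
    message(sprintf("split sizes: train=%d validation=%d test=%d",
                    counts[["train"]], counts[["validation"]], counts[["test"]]))
  }
  cls <- sort(unique(df$label[out$split == "train"]))
  meta <- parcel_meta(df)
  if (length(cls) < meta$n_classes) {
    warn("some classes are absent from the training split; class weights cannot be computed")
  }
  parcel_meta(out) <- meta
  out
}

#' Stack standardized series into a samples x bands x steps array
#'
#' Internal bridge between the tibble representation and the compiled
#' encoder, exported because the training and evaluation helpers in scripts
#' use it too.
#'
#' @param df A standardized parcel tibble.
#' @return A numeric array of dimension `c(nrow(df), n_bands, t_steps)`.
#' @export
series_array <- function(df) {
  t_steps <- nrow(df$series[[1]])
  nb <- ncol(df$series[[1]])
  if (any(vapply(df$series, nrow, integer(1)) != t_steps)) {
    abort("series must be standardized to a common length first")
  }
  arr <- array(0, dim = c(nrow(df), nb, t_steps))
  for (i in seq_len(nrow(df))) arr[i, , ] <- t(df$series[[i]])
  arr
}
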