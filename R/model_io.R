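# On-disk containers.
#
# A model container is a directory holding `manifest.json` (layer list,
# formats, approximation configuration; human-readable) plus one raw
# little-endian array per tensor under `tensors/`: float64 for float
# weights, uint16 for packed MSD payloads, int32 for Q-format raw integers.
# Quantized containers store only the packed payloads -- exactly what the
# hardware keeps in on-chip memory -- and the decoded weights are
# reconstructed bit-exactly at load time.
#
# A dataset container is a directory of 8-bit grayscale PNGs plus a
# `labels.csv` manifest (columns file, label, split).

.spec_to_list <- function(s) list(m = s$m, n = s$n, signed = s$signed)
.spec_from_list <- function(l) qformat(l$m, l$n, isTRUE(l$signed))

.write_tensor <- function(x, path, what) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (what == "double") {
    writeBin(as.numeric(x), con, size = 8L, endian = "little")
  } else if (what == "uint16") {
    v <- as.integer(x)
    writeBin(as.raw(rbind(v %% 256L, v %/% 256L)), con)
  } else if (what == "int32") {
    writeBin(as.integer(x), con, size = 4L, endian = "little")
  } else stop("unknown tensor storage type: ", what)
}

.read_tensor <- function(path, what, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  out <- switch(what,
    double = readBin(con, numeric(), n = n, size = 8L, endian = "little"),
    uint16 = {
      b <- matrix(as.integer(readBin(con, "raw", n = 2L * n)), nrow = 2L)
      if (ncol(b) != n) stop("truncated tensor file: ", path)
      b[1L, ] + 256L * b[2L, ]
    },
    int32 = readBin(con, integer(), n = n, size = 4L, endian = "little"),
    stop("unknown tensor storage type: ", what))
  if (length(out) != n) stop("truncated tensor file: ", path)
  as.numeric(out)
}

#' Write / read a model container
#'
#' Serializes a float or quantized model to a directory with a structured
#' `manifest.json` and raw little-endian tensor files; `read_model()`
#' restores it bit-exactly (round-trip tested). Quantized containers hold
#' only packed MSD payloads for conv/linear weights, plus Q-format raw
#' integers for biases and normalization parameters.
#'
#' @param model a [float_model] or [quantized_model].
#' @param dir target directory (created; an existing manifest is
#'   overwritten).
#' @return `write_model` returns `dir` invisibly; `read_model` returns the
#'   model object.
#' @export
write_model <- function(model, dir) {
  dir.create(file.path(dir, "tensors"), recursive = TRUE, showWarnings = FALSE)
  tdir <- file.path(dir, "tensors")
  man <- list(schema_version = 1L,
              kind = if (inherits(model, "quantized_model")) "quantized_model"
                     else if (inherits(model, "float_model")) "float_model"
                     else stop("unsupported model class"),
              input_shape = model$input_shape)
  if (man$kind == "quantized_model") {
    man$p <- model$p; man$W_M <- model$W_M; man$act_bits <- model$act_bits
    man$input_spec <- .spec_to_list(model$input_spec)
  }
  lay <- list()
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    e <- list(kind = l$kind)
    tag <- sprintf("L%02d", i)
    if (man$kind == "float_model") {
      if (!is.null(l$W)) {
        e$w_dim <- if (is.matrix(l$W)) dim(l$W) else dim(l$W)
        e$w_file <- paste0(tag, "_W.bin")
        .write_tensor(l$W, file.path(tdir, e$w_file), "double")
      }
      if (!is.null(l$b)) {
        e$b_file <- paste0(tag, "_b.bin"); e$b_len <- length(l$b)
        .write_tensor(l$b, file.path(tdir, e$b_file), "double")
      }
      for (f in c("stride", "pad", "size", "from",
                  "gamma", "beta", "mean", "var", "eps"))
        if (!is.null(l[[f]])) e[[f]] <- l[[f]]
      if (!is.null(l$max_val) && is.finite(l$max_val)) e$max_val <- l$max_val
    } else {
      e$in_spec <- .spec_to_list(l$in_spec)
      e$out_spec <- .spec_to_list(l$out_spec)
      if (!is.null(l$cfg)) {
        e$wspec <- .spec_to_list(l$cfg$qspec)
        e$w_dim <- l$w_dim
        e$payload_file <- paste0(tag, "_packed.bin")
        .write_tensor(l$payload, file.path(tdir, e$payload_file), "uint16")
        if (!is.null(l$b_raw)) {
          e$b_file <- paste0(tag, "_bias.bin"); e$b_len <- length(l$b_raw)
          e$b_spec <- .spec_to_list(l$b_spec)
          .write_tensor(l$b_raw, file.path(tdir, e$b_file), "int32")
        }
        e$stride <- l$stride; e$pad <- l$pad
      }
      if (l$kind == "batchnorm") {
        e$scale_spec <- .spec_to_list(l$scale_spec)
        e$n_channels <- length(l$scale_raw)
        e$scale_file <- paste0(tag, "_scale.bin")
        e$shift_file <- paste0(tag, "_shift.bin")
        .write_tensor(l$scale_raw, file.path(tdir, e$scale_file), "int32")
        .write_tensor(l$shift_raw, file.path(tdir, e$shift_file), "int32")
      }
      for (f in c("size", "from"))
        if (!is.null(l[[f]])) e[[f]] <- l[[f]]
      if (!is.null(l$max_val) && is.finite(l$max_val)) e$max_val <- l$max_val
    }
    lay[[i]] <- e
  }
  man$layers <- lay
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("not a model container (no manifest.json): ", dir)
  man <- tryCatch(jsonlite::read_json(mf, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e) stop("malformed manifest: ",
                                           conditionMessage(e)))
  if (is.null(man$kind) || !man$kind %in% c("float_model", "quantized_model"))
    stop("malformed manifest: missing or unknown model kind")
  tdir <- file.path(dir, "tensors")
  layers <- vector("list", length(man$layers))
  for (i in seq_along(man$layers)) {
    e <- man$layers[[i]]
    if (man$kind == "float_model") {
      l <- list(kind = e$kind)
      if (!is.null(e$w_file)) {
        w <- .read_tensor(file.path(tdir, e$w_file), "double",
                          prod(unlist(e$w_dim)))
        dim(w) <- unlist(e$w_dim)
        l$W <- if (length(dim(w)) == 2L) as.matrix(w) else w
      }
      if (!is.null(e$b_file))
        l$b <- .read_tensor(file.path(tdir, e$b_file), "double", e$b_len)
      for (f in c("stride", "pad", "max_val", "size", "from",
                  "gamma", "beta", "mean", "var", "eps"))
        if (!is.null(e[[f]])) l[[f]] <- unlist(e[[f]])
      if (e$kind == "relu" && is.null(l$max_val)) l$max_val <- Inf
      layers[[i]] <- l
    } else {
      l <- list(kind = e$kind,
                in_spec = .spec_from_list(e$in_spec),
                out_spec = .spec_from_list(e$out_spec))
      if (!is.null(e$payload_file)) {
        wdim <- unlist(e$w_dim)
        cfg <- approx_config(man$p, man$W_M, qspec = .spec_from_list(e$wspec))
        payload <- .read_tensor(file.path(tdir, e$payload_file), "uint16",
                                prod(wdim))
        d <- .unpack_vec(payload, cfg)
        l$cfg <- cfg
        l$payload <- payload
        l$w_raw <- array(.msd_decode_mat(d), wdim)
        l$w_dim <- wdim
        l$nnz <- sum(.msd_count_mat(d))
        if (!is.null(e$b_file)) {
          l$b_raw <- .read_tensor(file.path(tdir, e$b_file), "int32", e$b_len)
          l$b_spec <- .spec_from_list(e$b_spec)
        }
        l$stride <- e$stride; l$pad <- e$pad
      }
      if (e$kind == "batchnorm") {
        l$scale_spec <- .spec_from_list(e$scale_spec)
        l$scale_raw <- .read_tensor(file.path(tdir, e$scale_file), "int32",
                                    e$n_channels)
        l$shift_raw <- .read_tensor(file.path(tdir, e$shift_file), "int32",
                                    e$n_channels)
      }
      for (f in c("max_val", "size", "from"))
        if (!is.null(e[[f]])) l[[f]] <- unlist(e[[f]])
      if (e$kind == "relu" && is.null(l$max_val)) l$max_val <- Inf
      layers[[i]] <- l
    }
  }
  if (man$kind == "float_model") {
    float_model(layers, unlist(man$input_shape))
  } else {
    structure(list(layers = layers, p = as.integer(man$p),
                   W_M = as.integer(man$W_M),
                   act_bits = as.integer(man$act_bits),
                   input_spec = .spec_from_list(man$input_spec),
                   input_shape = unlist(man$input_shape)),
              class = "quantized_model")
  }
}

#' Write / read a dataset container
#'
#' The on-disk layout is a directory of 8-bit grayscale PNG images plus a
#' `labels.csv` manifest with columns `file`, `label`, `split`.
#'
#' @param dataset an `"msd_dataset"` from [make_dataset()] (or any list with
#'   `train`/`test` splits of `list(images, labels)`).
#' @param dir target directory.
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns
#'   a list with `train` and `test` splits (images as integer arrays
#'   `(H, W, 1, N)` in `0..255`).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (split in c("train", "test")) {
    sp <- dataset[[split]]
    if (is.null(sp)) next
    n <- dim(sp$images)[4L]
    for (j in seq_len(n)) {
      fn <- sprintf("%s_%04d.png", split, j)
      png::writePNG(sp$images[, , 1L, j] / 255,
                    file.path(dir, "images", fn))
      rows[[length(rows) + 1L]] <- data.frame(file = fn,
                                              label = sp$labels[j],
                                              split = split)
    }
  }
  man <- do.call(rbind, rows)
  utils::write.csv(man, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "labels.csv")
  if (!file.exists(mf)) stop("not a dataset container (no labels.csv): ", dir)
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  if (!all(c("file", "label", "split") %in% names(man)))
    stop("malformed labels.csv (need columns file, label, split)")
  out <- list()
  for (split in unique(man$split)) {
    sub <- man[man$split == split, , drop = FALSE]
    imgs <- NULL
    for (j in seq_len(nrow(sub))) {
      m <- png::readPNG(file.path(dir, "images", sub$file[j]))
      if (length(dim(m)) == 3L) m <- m[, , 1L]
      if (is.null(imgs)) imgs <- array(0L, c(dim(m), 1L, nrow(sub)))
      imgs[, , 1L, j] <- as.integer(round(m * 255))
    }
    out[[split]] <- list(images = imgs, labels = as.integer(sub$label))
  }
  out
}
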