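# File formats and the pipeline surface. Interchange units are fixed:
# time in us, concentrations in M; conversions happen only at the parser
# boundary (unit bugs dominate this domain).

#' Read a dipolar trace file
#'
#' Two formats: the package's plain-text dialect (two/three whitespace- or
#' comma-separated columns `t_us v_real [v_imag]`, `#`-prefixed
#' `key = value` header lines carrying metadata), and Bruker BES3T
#' (`.DSC` text descriptor + `.DTA` binary payload; pass the `.DSC` or
#' `.DTA` path). BES3T abscissas are converted to us from the descriptor's
#' unit.
#'
#' @param path File path.
#' @param format `"ascii"` or `"bes3t"`; guessed from the extension by
#'   default.
#' @return A [dipolar_trace] labelled `"raw"`.
#' @export
read_trace <- function(path, format = c("auto", "ascii", "bes3t")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(dsc|dta)$", path, ignore.case = TRUE)) "bes3t" else "ascii"
  if (format == "bes3t") return(read_bes3t(path))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^\\s*#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*\\S)\\s*$", h))[[1]]
    if (length(m) == 3L) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(val)) m[3] else val
    }
  }
  body <- lines[!hdr & nzchar(trimws(lines))]
  if (!length(body)) stop("parse error: no data rows in ", path)
  rows <- lapply(seq_along(body), function(i) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "[,[:space:]]+")[[1]]))
    if (anyNA(x) || length(x) < 2L || length(x) > 3L)
      stop(sprintf("parse error at data line %d of %s", i, path))
    x
  })
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) stop("parse error: ragged columns in ", path)
  m <- do.call(rbind, rows)
  dipolar_trace(m[, 1], m[, 2], v_imag = if (ncols == 3L) m[, 3],
                meta = meta, label = "raw")
}

#' Write a dipolar trace in the plain-text dialect
#'
#' @param trace A [dipolar_trace].
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "dipolar_trace"))
  con <- file(path, "w"); on.exit(close(con))
  for (k in names(trace$meta))
    if (is.numeric(trace$meta[[k]]) || is.character(trace$meta[[k]]))
      writeLines(sprintf("# %s = %s", k, format(trace$meta[[k]], digits = 17)), con)
  writeLines(sprintf("# label = %s", trace$label), con)
  m <- cbind(trace$t, trace$v_real, trace$v_imag)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Minimal BES3T reader: 1-D datasets, descriptor keys XPTS/XMIN/XWID/XUNI,
# IKKF (REAL|CPLX), IRFMT/IIFMT (D = float64, F = float32), BSEQ endianness.
read_bes3t <- function(path) {
  base <- sub("\\.(dsc|dta)$", "", path, ignore.case = TRUE)
  dsc <- paste0(base, if (grepl("\\.DSC$|\\.DTA$", path)) ".DSC" else ".dsc")
  dta <- paste0(base, if (grepl("\\.DSC$|\\.DTA$", path)) ".DTA" else ".dta")
  if (!file.exists(dsc)) stop("BES3T descriptor not found: ", dsc)
  if (!file.exists(dta)) stop("BES3T data file not found: ", dta)
  kv <- list()
  for (l in readLines(dsc, warn = FALSE)) {
    if (grepl("^[*#]", l) || !nzchar(trimws(l))) next
    m <- regmatches(l, regexec("^([A-Z0-9]+)\\s+(.*\\S)\\s*$", l))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- gsub("^'|'$", "", m[3])
  }
  need <- c("XPTS", "XMIN", "XWID")
  if (!all(need %in% names(kv)))
    stop("format error: DSC lacks ", paste(setdiff(need, names(kv)), collapse = ", "))
  npts <- as.integer(kv$XPTS)
  xmin <- as.numeric(kv$XMIN); xwid <- as.numeric(kv$XWID)
  cplx <- identical(toupper(kv$IKKF %||% "REAL"), "CPLX")
  fmt <- toupper(kv$IRFMT %||% "D")
  size <- if (fmt == "F") 4L else 8L
  endian <- if (identical(toupper(kv$BSEQ %||% "BIG"), "LIT")) "little" else "big"
  nvals <- npts * (1L + cplx)
  raw_n <- file.info(dta)$size
  if (raw_n != nvals * size)
    stop(sprintf("format error: DTA holds %d bytes, descriptor implies %d",
                 raw_n, nvals * size))
  con <- file(dta, "rb"); on.exit(close(con))
  v <- readBin(con, "double", n = nvals, size = size, endian = endian)
  unit <- tolower(kv$XUNI %||% "ns")
  scale <- switch(unit, "ns" = 1e-3, "us" = 1, "µs" = 1, "ms" = 1e3,
                  "s" = 1e6, stop("unsupported abscissa unit: ", unit))
  t_us <- (xmin + xwid * (seq_len(npts) - 1) / (npts - 1)) * scale
  if (cplx) {
    vr <- v[seq(1, nvals, by = 2)]; vi <- v[seq(2, nvals, by = 2)]
  } else { vr <- v; vi <- NULL }
  dipolar_trace(t_us, vr, v_imag = vi,
                meta = list(source = basename(dta), format = "bes3t"),
                label = "raw")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a titration manifest
#'
#' CSV with columns `series_label, sample_id, trace_path, protein_conc_M,
#' ligand_conc_M, averaging_time_h`. Sample ids must be unique and
#' concentrations positive.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("series_label", "sample_id", "trace_path", "protein_conc_M",
            "ligand_conc_M", "averaging_time_h")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$sample_id)) stop("manifest sample_ids must be unique")
  if (any(m$protein_conc_M <= 0) || any(m$ligand_conc_M < 0))
    stop("manifest concentrations must be positive")
  m
}

#' @param manifest Manifest data.frame.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Emits one trace file per sample (plain-text dialect), `manifest.csv`,
#' and `truth.json`.
#'
#' @param dataset A `titration_dataset`.
#' @param outdir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_titration <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "titration_dataset"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(dataset$traces))
  for (i in seq_along(dataset$traces)) {
    paths[i] <- file.path(outdir, paste0(dataset$manifest$sample_id[i], ".dat"))
    write_trace(dataset$traces[[i]], paths[i])
  }
  man <- dataset$manifest
  man$trace_path <- basename(paths)
  mp <- file.path(outdir, "manifest.csv")
  write_manifest(man, mp)
  jsonlite::write_json(dataset$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Default pipeline configuration
#'
#' All tunables of the processing/fitting pipeline with their defaults.
#' @return Named list.
#' @export
default_config <- function() {
  list(r_min = 1.5, r_max = 8, dr = 0.1,
       lambda = 0.3, bg_fit_start_frac = 0.35, bg_dim = "free",
       refine = 1, polish = FALSE, anchor_series = TRUE, zero_time = FALSE,
       invert = FALSE, validation_trials = 50,
       share_delta_max = FALSE, seed = 1)
}

#' Run the full titration pipeline
#'
#' Per sample: process the trace (phase, normalise, background-correct,
#' invert, extract modulation depth / noise / sensitivity); per series:
#' 1:1 ligand-depletion isotherm fit; across series: global shared-K_D
#' fit. Per-sample failures are caught, logged under `excluded` with the
#' error message, and never silently dropped (a failed analysis must stay
#' visible, mirroring how low-quality samples are excluded in practice).
#'
#' @param x A manifest data.frame (with resolvable `trace_path`s), the path
#'   to a manifest CSV, a `titration_dataset`, or a list of
#'   `titration_dataset`s.
#' @param config Configuration list, see [default_config()].
#' @param data_dir Directory trace paths are relative to (manifest input).
#' @return Report list: `samples` (data.frame), `series_fits`,
#'   `global` (a `binding_fit` or NULL), `excluded`, `config`,
#'   `n_series`, `n_samples`.
#' @export
run_pipeline <- function(x, config = default_config(), data_dir = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.character(x)) {
    if (is.null(data_dir)) data_dir <- dirname(x)
    x <- read_manifest(x)
  }
  if (inherits(x, "titration_dataset")) x <- list(x)
  if (is.list(x) && length(x) && inherits(x[[1]], "titration_dataset")) {
    traces <- unlist(lapply(x, function(d) d$traces), recursive = FALSE)
    manifest <- do.call(rbind, lapply(x, function(d) d$manifest))
  } else {
    manifest <- x
    traces <- lapply(manifest$trace_path, function(p) {
      if (!is.null(data_dir) && !file.exists(p)) p <- file.path(data_dir, p)
      tryCatch(read_trace(p), error = function(e) e)
    })
  }
  r_grid <- seq(cfg$r_min, cfg$r_max, by = cfg$dr)
  bg_d <- if (identical(cfg$bg_dim, "free")) NULL else as.numeric(sub("^fixed:", "", cfg$bg_dim))

  rows <- list(); excluded <- list()
  # process series-wise: the anchor scheme shares the distribution and the
  # background dimensionality within a series (see process_series)
  for (lab in unique(manifest$series_label)) {
    idx <- which(manifest$series_label == lab)
    idx <- idx[order(manifest$ligand_conc_M[idx])]
    bad <- vapply(traces[idx], inherits, logical(1), "error")
    for (i in idx[bad])
      excluded[[length(excluded) + 1L]] <-
        list(sample_id = manifest$sample_id[i],
             reason = conditionMessage(traces[[i]]))
    idx <- idx[!bad]
    if (!length(idx)) next
    results <- if (isTRUE(cfg$anchor_series) && length(idx) > 1L) {
      tryCatch(process_series(traces[idx], r_grid = r_grid,
                              lambda = cfg$lambda, refine = cfg$refine,
                              polish = isTRUE(cfg$polish),
                              zero_time = isTRUE(cfg$zero_time)),
               error = function(e) e)
    } else NULL
    if (is.null(results) || inherits(results, "error")) {
      results <- lapply(idx, function(i) tryCatch(
        process_trace(traces[[i]], r_grid = r_grid, lambda = cfg$lambda,
                      bg_d = bg_d, refine = cfg$refine,
                      polish = isTRUE(cfg$polish),
                      zero_time = isTRUE(cfg$zero_time)),
        error = function(e) e))
    }
    for (j in seq_along(idx)) {
      i <- idx[j]
      res <- results[[j]]
      if (inherits(res, "error")) {
        excluded[[length(excluded) + 1L]] <-
          list(sample_id = manifest$sample_id[i],
               reason = conditionMessage(res))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        series_label = manifest$series_label[i],
        sample_id = manifest$sample_id[i],
        protein_conc_M = manifest$protein_conc_M[i],
        ligand_conc_M = manifest$ligand_conc_M[i],
        averaging_time_h = manifest$averaging_time_h[i],
        delta = res$delta, delta_se = res$delta_se,
        noise_rms = res$noise_rms, sensitivity = res$sensitivity,
        bg_k = res$background$k, bg_d = res$background$d,
        stringsAsFactors = FALSE)
    }
  }
  samples <- if (length(rows)) do.call(rbind, rows) else NULL
  series_fits <- list(); series_objs <- list()
  if (!is.null(samples)) {
    for (lab in unique(samples$series_label)) {
      s <- samples[samples$series_label == lab, ]
      if (nrow(s) < 4L) next
      ser <- titration_series(s$protein_conc_M[1], s$ligand_conc_M,
                              pmin(1, pmax(0, s$delta)),
                              pmax(s$delta_se, 1e-6), label = lab)
      series_objs[[lab]] <- ser
      series_fits[[lab]] <- tryCatch(fit_isotherm(ser), error = function(e) e)
    }
  }
  glob <- if (length(series_objs) >= 2L)
    tryCatch(global_fit(unname(series_objs),
                        share_delta_max = isTRUE(cfg$share_delta_max)),
             error = function(e) e) else NULL
  # replicate series realise the correlated (per-series) processing error
  # that the profile CI, which assumes independent point errors, cannot
  # see; widen the reported intervals by the between-series scatter of the
  # per-series estimates (random-effects style)
  ok_fits <- Filter(function(f) inherits(f, "binding_fit"), series_fits)
  if (inherits(glob, "binding_fit") && length(ok_fits) >= 2L) {
    lk <- log10(vapply(ok_fits, function(f) f$kd, numeric(1)))
    m <- mean(lk); se <- stats::sd(lk) / sqrt(length(lk))
    widen <- function(ci, q) {
      hw <- stats::qt(q, df = length(lk) - 1L) * se
      c(min(ci[1], 10^(m - hw)), max(ci[2], 10^(m + hw)))
    }
    glob$ci68_kd <- widen(glob$ci68_kd, 0.84)
    glob$ci95_kd <- widen(glob$ci95_kd, 0.975)
    glob$ci_includes_between_series <- TRUE
  }
  list(samples = samples, series_fits = series_fits, global = glob,
       excluded = excluded, config = cfg,
       n_series = length(series_objs),
       n_samples = if (is.null(samples)) 0L else nrow(samples))
}
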