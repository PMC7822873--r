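#' Read an LCModel-style RAW file
#'
#' Parses the NMID-style header block (a Fortran namelist: lines between
#' `$NMID` and `$END`), then whitespace-separated (real, imaginary) pairs.
#' Bare files without a namelist are accepted (all values taken as data).
#' Header fields recognized: `HZPPPM` (Larmor MHz), `DELTAT` (dwell time s),
#' `PPMCEN` (carrier ppm); anything missing falls back to `default_header`.
#'
#' @param path File path.
#' @param default_header Optional [acq_header()] supplying fields the file
#'   lacks (required for bare files).
#' @return An [mrs_fid()].
#' @export
read_lcmodel_raw <- function(path, default_header = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr_fields <- list()
  data_start <- 1L
  in_nml <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^\\$(NMID|SEQPAR)", ln, ignore.case = TRUE)) {
      in_nml <- TRUE
      next
    }
    if (in_nml) {
      if (grepl("^\\$END", ln, ignore.case = TRUE)) {
        in_nml <- FALSE
        data_start <- i + 1L
        next
      }
      kv <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*('.*'|[^,]*)", ln))[[1]]
      if (length(kv) == 3) {
        hdr_fields[[toupper(kv[2])]] <- gsub("'", "", kv[3])
      } else if (nzchar(ln)) {
        stop(sprintf("parse error at line %d: malformed header line '%s'", i, ln),
             call. = FALSE)
      }
      next
    }
  }
  if (in_nml) stop("parse error: header block not terminated by $END", call. = FALSE)
  vals <- suppressWarnings(as.numeric(unlist(strsplit(
    paste(lines[data_start:length(lines)], collapse = " "), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("parse error: no data values found", call. = FALSE)
  if (length(vals) %% 2 != 0)
    stop("parse error: odd number of values (expected real/imaginary pairs)", call. = FALSE)
  n <- length(vals) / 2
  larmor <- if (!is.null(hdr_fields$HZPPPM)) as.numeric(hdr_fields$HZPPPM)
            else default_header$larmor_mhz
  bw <- if (!is.null(hdr_fields$DELTAT)) 1 / as.numeric(hdr_fields$DELTAT)
        else default_header$bandwidth_hz
  cen <- if (!is.null(hdr_fields$PPMCEN)) as.numeric(hdr_fields$PPMCEN)
         else if (!is.null(default_header)) default_header$center_ppm else 4.65
  if (is.null(larmor) || is.null(bw))
    stop("parse error: file lacks HZPPPM/DELTAT and no default header given", call. = FALSE)
  h <- acq_header(larmor, bw, n, cen)
  mrs_fid(complex(real = vals[c(TRUE, FALSE)], imaginary = vals[c(FALSE, TRUE)]), h)
}

#' Write an LCModel-style RAW file
#'
#' Emits the canonical dialect of this package: a `$NMID` namelist carrying
#' `ID`, `HZPPPM`, `DELTAT` and `PPMCEN`, then one `(real, imaginary)` pair
#' per line in `%15.6E` format (round trips with [read_lcmodel_raw()] to
#' 1e-6 relative).
#'
#' @param fid An [mrs_fid()].
#' @param path Output path.
#' @param id ID string stored in the header.
#' @return `path`, invisibly.
#' @export
write_lcmodel_raw <- function(fid, path, id = "mrsproc") {
  if (!inherits(fid, "mrs_fid")) stop("'fid' must be an mrs_fid", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(" $NMID",
               sprintf(" ID='%s'", id),
               sprintf(" HZPPPM=%.6f", fid$header$larmor_mhz),
               sprintf(" DELTAT=%.9e", 1 / fid$header$bandwidth_hz),
               sprintf(" PPMCEN=%.4f", fid$header$center_ppm),
               " FMTDAT='(2E15.6)'",
               " $END"), con)
  writeLines(sprintf("%15.6E%15.6E", Re(fid$samples), Im(fid$samples)), con)
  invisible(path)
}

#' Read an LCModel-style BASIS file
#'
#' Accepts the package's canonical dialect: a `$BASIS1` block with
#' `HZPPPM`, `BADELT` (dwell s), `NDATAB` and `PPMCEN`, followed by one
#' `$BASIS` block per metabolite (`METABO='name'` ... `$END`, then NDATAB
#' real/imaginary pairs).
#'
#' @param path File path.
#' @return A [basis_set()].
#' @export
read_lcmodel_basis <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  n_lines <- length(lines)
  global <- list()
  read_block <- function(i) {
    fields <- list()
    while (i <= n_lines) {
      ln <- trimws(lines[i])
      if (grepl("^\\$END", ln, ignore.case = TRUE)) return(list(fields = fields, i = i + 1L))
      kv <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*('.*'|[^,]*)", ln))[[1]]
      if (length(kv) == 3) fields[[toupper(kv[2])]] <- gsub("'", "", kv[3])
      i <- i + 1L
    }
    stop("parse error: block missing $END terminator", call. = FALSE)
  }
  # global header
  while (i <= n_lines && !grepl("^\\s*\\$BASIS1", lines[i], ignore.case = TRUE)) i <- i + 1L
  if (i > n_lines) stop("parse error: no $BASIS1 block found", call. = FALSE)
  b <- read_block(i + 1L)
  global <- b$fields
  i <- b$i
  for (f in c("HZPPPM", "BADELT", "NDATAB"))
    if (is.null(global[[f]])) stop("parse error: $BASIS1 lacks ", f, call. = FALSE)
  ndat <- as.integer(as.numeric(global$NDATAB))
  h <- acq_header(as.numeric(global$HZPPPM), 1 / as.numeric(global$BADELT), ndat,
                  if (!is.null(global$PPMCEN)) as.numeric(global$PPMCEN) else 4.65)
  entries <- list()
  while (i <= n_lines) {
    if (grepl("^\\s*\\$BASIS\\b", lines[i], ignore.case = TRUE)) {
      b <- read_block(i + 1L)
      i <- b$i
      nm <- b$fields$METABO
      if (is.null(nm)) stop("parse error: $BASIS block lacks METABO", call. = FALSE)
      if (nm %in% names(entries)) stop("parse error: duplicate metabolite '", nm, "'",
                                       call. = FALSE)
      vals <- numeric(0)
      while (length(vals) < 2 * ndat && i <= n_lines &&
             !grepl("^\\s*\\$", lines[i])) {
        v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
        vals <- c(vals, v[!is.na(v)])
        i <- i + 1L
      }
      if (length(vals) < 2 * ndat)
        stop("parse error: metabolite '", nm, "' has fewer than NDATAB pairs", call. = FALSE)
      entries[[nm]] <- complex(real = vals[c(TRUE, FALSE)], imaginary = vals[c(FALSE, TRUE)])
    } else i <- i + 1L
  }
  if (length(entries) == 0L) stop("parse error: no $BASIS blocks found", call. = FALSE)
  meta <- list()
  if (!is.null(global$SEQ)) meta$sequence <- global$SEQ
  if (!is.null(global$ECHOT)) meta$te_ms <- as.numeric(global$ECHOT)
  basis_set(entries, h, meta)
}

#' Write an LCModel-style BASIS file
#'
#' @param basis A [basis_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lcmodel_basis <- function(basis, path) {
  if (!inherits(basis, "basis_set")) stop("'basis' must be a basis_set", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  h <- basis$header
  writeLines(c(" $BASIS1",
               sprintf(" HZPPPM=%.6f", h$larmor_mhz),
               sprintf(" BADELT=%.9e", 1 / h$bandwidth_hz),
               sprintf(" NDATAB=%d", h$n_points),
               sprintf(" PPMCEN=%.4f", h$center_ppm),
               if (!is.null(basis$metadata$sequence))
                 sprintf(" SEQ='%s'", basis$metadata$sequence),
               if (!is.null(basis$metadata$te_ms) && is.finite(basis$metadata$te_ms))
                 sprintf(" ECHOT=%.2f", basis$metadata$te_ms),
               " $END"), con)
  for (nm in names(basis$entries)) {
    writeLines(c(" $BASIS", sprintf(" METABO='%s'", nm), " $END"), con)
    v <- basis$entries[[nm]]
    writeLines(sprintf("%15.6E%15.6E", Re(v), Im(v)), con)
  }
  invisible(path)
}

# --- native JSON container -------------------------------------------------

NATIVE_SCHEMA <- "mrsproc-native-1"

header_to_list <- function(h)
  list(larmor_mhz = h$larmor_mhz, bandwidth_hz = h$bandwidth_hz,
       n_points = h$n_points, center_ppm = h$center_ppm,
       te_ms = h$te_ms, tr_ms = h$tr_ms, tm_ms = h$tm_ms)

header_from_list <- function(l)
  acq_header(l$larmor_mhz, l$bandwidth_hz, l$n_points, l$center_ppm,
             l$te_ms %||% NA_real_, l$tr_ms %||% NA_real_, l$tm_ms %||% NA_real_)

cplx_out <- function(v) list(re = Re(v), im = Im(v))
cplx_in <- function(l) complex(real = unlist(l$re), imaginary = unlist(l$im))

#' Native single-file container
#'
#' Lossless JSON serialization of the package's objects: FIDs, spectra,
#' datasets (including condition labels and water references) and basis
#' sets, together with an append-only processing log of applied operations.
#' The schema id is `mrsproc-native-1`; complex data are stored as parallel
#' `re`/`im` arrays.
#'
#' @param obj An [mrs_fid()], [mrs_spectrum()], [mrs_dataset()] or
#'   [basis_set()].
#' @param path Output path (conventionally `.json`).
#' @param proc_log Optional list of log entries (each a named list of an
#'   operation and its parameters), appended to any log already on `obj`.
#' @return `path`, invisibly.
#' @export
write_native <- function(obj, path, proc_log = list()) {
  doc <- list(schema = NATIVE_SCHEMA)
  if (inherits(obj, "mrs_fid")) {
    doc$kind <- "fid"
    doc$header <- header_to_list(obj$header)
    doc$data <- cplx_out(obj$samples)
  } else if (inherits(obj, "mrs_spectrum")) {
    doc$kind <- "spectrum"
    doc$header <- header_to_list(obj$header)
    doc$data <- cplx_out(obj$values)
  } else if (inherits(obj, "mrs_dataset")) {
    doc$kind <- "dataset"
    doc$header <- header_to_list(obj$header)
    d <- dim(obj$data)
    doc$dims <- d
    doc$data <- cplx_out(as.vector(obj$data))
    doc$condition_labels <- obj$condition_labels
    if (!is.null(obj$water_refs)) {
      doc$water_refs <- cplx_out(as.vector(obj$water_refs))
    }
  } else if (inherits(obj, "basis_set")) {
    doc$kind <- "basis"
    doc$header <- header_to_list(obj$header)
    doc$metadata <- obj$metadata
    doc$entries <- lapply(obj$entries, cplx_out)
  } else stop("unsupported object for native container", call. = FALSE)
  doc$proc_log <- c(attr(obj, "proc_log") %||% list(), proc_log)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' @rdname write_native
#' @return For `read_native()`: the reconstructed object, with the
#'   processing log attached as attribute `proc_log`.
#' @export
read_native <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(doc$schema, NATIVE_SCHEMA))
    stop("schema mismatch: expected ", NATIVE_SCHEMA, ", found ",
         doc$schema %||% "<none>", call. = FALSE)
  h <- header_from_list(doc$header)
  obj <- switch(doc$kind,
    fid = mrs_fid(cplx_in(doc$data), h),
    spectrum = mrs_spectrum(cplx_in(doc$data), h),
    dataset = {
      d <- unlist(doc$dims)
      cube <- array(cplx_in(doc$data), d)
      w <- if (!is.null(doc$water_refs)) matrix(cplx_in(doc$water_refs), d[2], d[3])
      mrs_dataset(cube, h, unlist(doc$condition_labels), w)
    },
    basis = basis_set(lapply(doc$entries, cplx_in), h, doc$metadata %||% list()),
    stop("schema mismatch: unknown kind '", doc$kind, "'", call. = FALSE))
  attr(obj, "proc_log") <- doc$proc_log %||% list()
  obj
}

#' @rdname write_native
#' @param basis A [basis_set()].
#' @export
write_basis_native <- function(basis, path) write_native(basis, path)

#' @rdname write_native
#' @export
read_basis_native <- function(path) {
  obj <- read_native(path)
  if (!inherits(obj, "basis_set")) stop("schema mismatch: file is not a basis", call. = FALSE)
  obj
}

# --- protocol files --------------------------------------------------------

PROTOCOL_SCHEMA <- "mrsproc-protocol-1"

protocol_defaults <- function() {
  list(
    preprocess = list(method = "klose", weighting = "sensitivity",
                      align = list(enabled = TRUE, windows = list(c(0, 4.2)),
                                   freq_range_hz = 10, freq_resolution_hz = 0.5,
                                   phase_step_deg = 2, amp_poly_order = 0,
                                   reference = "mean"),
                      keep = "all"),
    process = list(lorentz_hz = 0, gauss_hz = 0, zero_fill = 0, cut = 0,
                   phase0_deg = 0, phase1_deg_per_ppm = 0, pivot_ppm = NULL,
                   hsvd = list(enabled = FALSE, order = 20, band = c(4.2, 5.1)),
                   baseline = list(enabled = FALSE, order = 2, anchors = list())),
    synthesis = list(singlets = list(), noise_sd = 0, baseline = list(), seed = 1),
    simulate = list(sequence = "press", te_ms = 30, tm_ms = 10, loc = "ideal",
                    n_spatial = 8, metabolites = list()),
    lcm = list(window = c(0.5, 4.2), baseline_order = 2, domain = "complex",
               tol = 1e-8, max_iter = 100, noise_window = c(8, 10),
               fit_shifts = TRUE, fit_lorentz = TRUE, fit_gauss = FALSE,
               fit_phase0 = TRUE, fit_phase1 = FALSE)
  )
}

merge_protocol <- function(defaults, user, path = character(0)) {
  applied <- character(0)
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop("unknown protocol key(s): ", paste(c(path, nm), collapse = "$"), call. = FALSE)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) && is.list(user[[nm]])) {
      res <- merge_protocol(defaults[[nm]], user[[nm]], c(path, nm))
      defaults[[nm]] <- res$value
      applied <- c(applied, res$applied)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  missing <- setdiff(names(defaults), names(user))
  if (length(missing))
    applied <- c(applied, paste(c(path, ""), collapse = "$") |>
                   paste0(missing))
  list(value = defaults, applied = applied)
}

#' Save / load a protocol file
#'
#' A protocol captures every user-settable parameter of every processing
#' stage in one human-readable, diffable JSON document (schema
#' `mrsproc-protocol-1`), so a pipeline can be re-run bit-identically at
#' another site. Loading validates keys against the known parameter tree:
#' unknown keys are an error naming them; missing sections fall back to
#' defaults and are recorded in the returned `applied_defaults`; a schema
#' mismatch sets an explicit `version_warning` field.
#'
#' @param config Named list of sections (`preprocess`, `process`,
#'   `synthesis`, `simulate`, `lcm`), each a partial or full parameter
#'   list; see `protocol_defaults` in the sources for the tree.
#' @param path File path.
#' @return `save_protocol`: `path`, invisibly. `load_protocol`: list with
#'   `config` (fully merged), `applied_defaults` (character vector of keys
#'   defaulted) and optionally `version_warning`.
#' @export
save_protocol <- function(config, path) {
  merged <- merge_protocol(protocol_defaults(), config)
  doc <- list(schema = PROTOCOL_SCHEMA, config = merged$value)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_protocol
#' @export
load_protocol <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  out <- list()
  if (!identical(doc$schema, PROTOCOL_SCHEMA))
    out$version_warning <- sprintf("protocol schema '%s' differs from expected '%s'",
                                   doc$schema %||% "<none>", PROTOCOL_SCHEMA)
  merged <- merge_protocol(protocol_defaults(), doc$config %||% list())
  out$config <- merged$value
  out$applied_defaults <- merged$applied
  out
}
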