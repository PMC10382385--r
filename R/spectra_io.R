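# Plain-text MS2 spectrum formats: MGF and MSP.

#' Read spectra from an MGF or MSP file
#'
#' Dispatches on the file extension; `.mgf` goes to [read_mgf()], `.msp` to
#' [read_msp()].
#'
#' @param path File path.
#' @return List of [ms2_spectrum()] objects (empty list for an empty file).
#' @export
read_spectra <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         mgf = read_mgf(path),
         msp = read_msp(path),
         stop("unsupported spectrum format: .", ext, call. = FALSE))
}

#' @rdname read_spectra
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  block <- NULL
  block_n <- 0L
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "BEGIN IONS") {
      block <- character(0)
    } else if (ln == "END IONS") {
      block_n <- block_n + 1L
      sp <- tryCatch(parse_mgf_block(block),
                     error = function(e) {
                       message("skipping malformed MGF block ", block_n,
                               ": ", conditionMessage(e))
                       NULL
                     })
      if (!is.null(sp)) out[[length(out) + 1L]] <- sp
      block <- NULL
    } else if (!is.null(block) && nzchar(ln)) {
      block <- c(block, ln)
    }
  }
  out
}

parse_mgf_block <- function(block) {
  kv <- grepl("=", block, fixed = TRUE)
  keys <- toupper(sub("=.*$", "", block[kv]))
  vals <- sub("^[^=]*=", "", block[kv])
  precursor <- NA_real_
  rt <- NA_real_
  name <- NA_character_
  if ("PEPMASS" %in% keys) {
    # PEPMASS may carry "mz intensity"
    precursor <- as.numeric(strsplit(vals[match("PEPMASS", keys)],
                                     "[ \t]+")[[1]][1])
  }
  if ("RTINSECONDS" %in% keys) rt <- as.numeric(vals[match("RTINSECONDS", keys)])
  if ("TITLE" %in% keys) name <- vals[match("TITLE", keys)]
  pk <- do.call(rbind, lapply(block[!kv], function(x) {
    as.numeric(strsplit(x, "[ \t]+")[[1]][1:2])
  }))
  if (is.null(pk) || anyNA(pk)) stop("no valid peak lines")
  ms2_spectrum(pk[, 1], pk[, 2], precursor_mz = precursor, rt = rt,
               name = name)
}

#' @rdname read_spectra
#' @export
read_msp <- function(path) {
  lines <- c(readLines(path, warn = FALSE), "")
  out <- list()
  fields <- list()
  peaks <- list()
  entry_n <- 0L
  flush <- function() {
    if (!length(fields) && !length(peaks)) return(invisible())
    entry_n <<- entry_n + 1L
    sp <- tryCatch({
      pk <- do.call(rbind, peaks)
      if (is.null(pk) || anyNA(pk)) stop("no valid peak lines")
      ms2_spectrum(pk[, 1], pk[, 2],
                   precursor_mz = as.numeric(
                     fields[["PRECURSORMZ"]] %||% NA_real_),
                   rt = as.numeric(fields[["RETENTIONTIME"]] %||% NA_real_),
                   name = fields[["NAME"]] %||% NA_character_)
    }, error = function(e) {
      message("skipping malformed MSP entry ", entry_n, ": ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(sp)) out[[length(out) + 1L]] <<- sp
    fields <<- list()
    peaks <<- list()
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) {
      flush()
    } else if (grepl("^[A-Za-z][A-Za-z0-9 _]*:", ln)) {
      key <- toupper(gsub("[ _]", "", sub(":.*$", "", ln)))
      val <- trimws(sub("^[^:]*:", "", ln))
      if (key == "NAME" && length(fields)) flush() # entries not blank-separated
      fields[[key]] <- val
    } else {
      v <- as.numeric(strsplit(ln, "[ \t;]+")[[1]][1:2])
      peaks[[length(peaks) + 1L]] <- v
    }
  }
  flush()
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write spectra to MGF or MSP
#'
#' @param spectra List of [ms2_spectrum()] objects.
#' @param path Output file path.
#' @name write_spectra
NULL

#' @rdname write_spectra
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.na(s$name)) writeLines(paste0("TITLE=", s$name), con)
    if (!is.na(s$precursor_mz)) {
      writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    }
    if (!is.na(s$rt)) writeLines(sprintf("RTINSECONDS=%.3f", s$rt), con)
    writeLines(sprintf("%.5f %.6g", s$mz, s$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' @rdname write_spectra
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(paste0("Name: ", if (is.na(s$name)) "unknown" else s$name),
               con)
    if (!is.na(s$precursor_mz)) {
      writeLines(sprintf("PrecursorMZ: %.6f", s$precursor_mz), con)
    }
    if (!is.na(s$rt)) writeLines(sprintf("RetentionTime: %.3f", s$rt), con)
    writeLines(sprintf("Num Peaks: %d", length(s$mz)), con)
    writeLines(sprintf("%.5f %.6g", s$mz, s$intensity), con)
    writeLines("", con)
  }
  invisible(path)
}
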