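#' Write a dataset in the grouped-spectrum ASCII dialect
#'
#' A plain-text, diffable exchange format: `#`-prefixed header lines carry
#' metadata (`temperature_K`, `label`, plus any extra keys), followed by
#' one block per Q introduced by `# Q = <value> invA` and three
#' whitespace-separated columns `E(meV) S dS`.  Numbers are written with
#' `%.17g` so a read/write round trip reproduces every double bit-exactly,
#' and the formatting is deterministic (fixed column order, ascending Q
#' blocks): writing the same dataset twice yields identical bytes.
#'
#' @param ds A `qens_dataset`.
#' @param path Output file path.
#' @param extra Named character vector of additional header keys to
#'   preserve.
#' @return `path`, invisibly.
#' @seealso [read_grouped()]
#' @export
write_grouped <- function(ds, path, extra = NULL) {
  if (is.null(ds) || nrow(ds) == 0) {
    abort("cannot write an empty dataset", class = "qens_validation_error")
  }
  df <- dplyr::arrange(tibble::as_tibble(ds), .data$q, .data$energy)
  lines <- c(
    "# qensmem grouped spectra v1",
    sprintf("# temperature_K = %.17g", qens_temperature(ds)),
    sprintf("# label = %s", qens_label(ds))
  )
  if (!is.null(extra)) {
    lines <- c(lines, sprintf("# %s = %s", names(extra), unname(extra)))
  }
  for (qi in unique(df$q)) {
    blk <- df[df$q == qi, ]
    lines <- c(lines,
               sprintf("# Q = %.17g invA", qi),
               sprintf("%.17g %.17g %.17g",
                       blk$energy, blk$intensity, blk$uncertainty))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a grouped-spectrum ASCII file
#'
#' Parses the dialect written by [write_grouped()], validates the spectrum
#' invariants (strictly increasing energy per block, >= 8 points,
#' non-negative errors, Q within the instrument sanity range) and attaches
#' the metadata.  Unknown header keys are preserved in the
#' `"extra_header"` attribute.  Files whose energy column looks like
#' micro-eV (values far outside a few meV) are rejected with a unit hint.
#'
#' @param path Input file path.
#' @return A `qens_dataset`.
#' @export
read_grouped <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "qens_io_error")
  }
  lines <- readLines(path)
  temperature <- NA_real_
  label <- ""
  extra <- character(0)
  blocks <- list()
  cur_q <- NA_real_
  cur_rows <- list()
  flush_block <- function() {
    if (is.na(cur_q)) return()
    if (length(cur_rows) == 0) {
      abort(sprintf("empty block at Q = %g", cur_q), class = "qens_parse_error")
    }
    m <- do.call(rbind, cur_rows)
    blocks[[length(blocks) + 1]] <<- tibble::tibble(
      q = cur_q, energy = m[, 1], intensity = m[, 2], uncertainty = m[, 3])
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#", "", ln))
      if (grepl("^Q\\s*=", body)) {
        flush_block()
        cur_q <- suppressWarnings(as.numeric(strsplit(body, "\\s+")[[1]][3]))
        if (is.na(cur_q)) {
          abort(sprintf("line %d: malformed Q header '%s'", i, ln),
                class = "qens_parse_error")
        }
        cur_rows <- list()
      } else if (grepl("=", body, fixed = TRUE)) {
        kv <- strsplit(body, "=", fixed = TRUE)[[1]]
        key <- trimws(kv[1])
        val <- trimws(paste(kv[-1], collapse = "="))
        if (key == "temperature_K") temperature <- as.numeric(val)
        else if (key == "label") label <- val
        else extra[key] <- val
      }
      next
    }
    vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
    if (length(vals) != 3 || any(is.na(vals))) {
      abort(sprintf("line %d: expected 'E S dS', got '%s'", i, ln),
            class = "qens_parse_error")
    }
    if (is.na(cur_q)) {
      abort(sprintf("line %d: data before any '# Q =' header", i),
            class = "qens_parse_error")
    }
    cur_rows[[length(cur_rows) + 1]] <- vals
  }
  flush_block()
  if (length(blocks) == 0) {
    abort("file contains no spectrum blocks", class = "qens_parse_error")
  }
  if (is.na(temperature)) {
    abort("missing temperature_K header", class = "qens_validation_error")
  }
  df <- dplyr::bind_rows(blocks)
  if (max(abs(df$energy)) > 50) {
    abort("energy column looks mis-scaled (expected meV; is this file in micro-eV?)",
          class = "qens_validation_error")
  }
  for (qi in unique(df$q)) {
    e <- df$energy[df$q == qi]
    if (any(diff(e) <= 0)) {
      abort(sprintf("block Q = %g: energy column not strictly increasing", qi),
            class = "qens_parse_error")
    }
  }
  ds <- qens_dataset(df, temperature = temperature, label = label)
  if (length(extra) > 0) attr(ds, "extra_header") <- extra
  ds
}

#' Export the confined-diffusion eigenvalue table as TSV
#'
#' @param eig Eigenvalue table from [vd_eigenvalues()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eigensystem_tsv <- function(eig, path) {
  utils::write.table(
    data.frame(l = eig$l, n = eig$n, x_nl = sprintf("%.12g", eig$x)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
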