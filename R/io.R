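#' Read tabular pipeline inputs
#'
#' Thin readers over comma-separated files (UTF-8, header required, `.`
#' decimal) that validate the expected columns and return tibbles in the
#' package's column conventions.
#'
#' * barrier tables: `temperature_C,dG_mean[,dG_sem,n_replicates]` or the
#'   replicate-level `temperature_C,replicate,dG`;
#' * ramp traces: `time_s,temperature_C,absorbance`;
#' * steady-state tables: `substrate_uM,velocity[,replicate]`;
#' * distance series: `frame,distance_A` (or a single `distance_A` column);
#' * trajectories: long CSV `frame,atom,residue[,name],x,y,z`, or a
#'   multi-frame XYZ-like text file (per frame: an atom-count line, a
#'   comment line, then `name residue x y z` records).
#'
#' @param path file path.
#' @return a tibble (see above for columns).
#' @name topt-io
NULL

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(out))
  if (length(miss)) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname topt-io
#' @export
read_barrier_table <- function(path) {
  out <- .read_csv_checked(path, "temperature_C")
  if (!("dG_mean" %in% names(out) || "dG" %in% names(out))) {
    stop("missing column(s) in ", basename(path), ": dG_mean (or dG)",
         call. = FALSE)
  }
  out
}

#' @rdname topt-io
#' @export
read_ramp_trace <- function(path) {
  .read_csv_checked(path, c("time_s", "temperature_C", "absorbance"))
}

#' @rdname topt-io
#' @export
read_mm_table <- function(path) {
  .read_csv_checked(path, c("substrate_uM", "velocity"))
}

#' @rdname topt-io
#' @export
read_distance_series <- function(path) {
  .read_csv_checked(path, "distance_A")
}

#' @rdname topt-io
#' @export
read_trajectory <- function(path) {
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    .read_trajectory_xyz(path)
  } else {
    out <- .read_csv_checked(path, c("frame", "atom", "residue", "x", "y", "z"))
    attr(out, "superposed") <- FALSE
    out
  }
}

# multi-frame XYZ-like reader: blocks of [natoms, comment, natoms records];
# records are `name residue x y z` (or plain `name x y z`, residue = atom id)
.read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  i <- 1L; frame <- 0L; rows <- list()
  while (i <= length(lines)) {
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na) || na < 1) {
      stop("malformed XYZ file at line ", i, ": expected an atom count",
           call. = FALSE)
    }
    if (i + 1 + na > length(lines)) {
      stop("truncated XYZ frame starting at line ", i, call. = FALSE)
    }
    frame <- frame + 1L
    block <- lines[(i + 2):(i + 1 + na)]
    tok <- strsplit(trimws(block), "\\s+")
    nf <- lengths(tok)
    if (!all(nf %in% c(4L, 5L))) {
      stop("malformed XYZ atom record in frame ", frame, call. = FALSE)
    }
    has_res <- nf == 5L
    rows[[frame]] <- tibble::tibble(
      frame = frame,
      atom = seq_len(na),
      residue = ifelse(has_res,
                       suppressWarnings(as.integer(vapply(tok, `[`, "", 2))),
                       seq_len(na)),
      name = vapply(tok, `[`, "", 1),
      x = as.numeric(vapply(tok, function(t) t[length(t) - 2], "")),
      y = as.numeric(vapply(tok, function(t) t[length(t) - 1], "")),
      z = as.numeric(vapply(tok, function(t) t[length(t)], ""))
    )
    i <- i + 2L + na
  }
  out <- dplyr::bind_rows(rows)
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    stop("malformed XYZ coordinates", call. = FALSE)
  }
  attr(out, "superposed") <- FALSE
  out
}

# ---- JSON results -----------------------------------------------------------

# All CLI outputs share an envelope carrying the package version and an
# md5 of each input so that runs are traceable; no timestamps, so repeated
# seeded runs are byte-identical.
.result_envelope <- function(inputs = character()) {
  list(
    software = "topt",
    version = as.character(utils::packageVersion("topt")),
    schema = "topt-result/1",
    inputs = if (length(inputs)) {
      lapply(inputs, function(p) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      })
    } else {
      list()
    }
  )
}

.write_result_json <- function(x, path = NULL) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null", pretty = TRUE)
  if (is.null(path)) cat(json, "\n") else writeLines(json, path)
  invisible(json)
}
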