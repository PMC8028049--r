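# Weighted training/validation entries and their tab-separated carrier
# format. An entry references structures by id; the reax_trainset object
# pairs the entry table with a named list of structures so the cost function
# can evaluate each entry.
#
# TSV schema (one header line, tab-separated):
#   id  kind  structure_ids  detail  reference  weight  partition
# kind: energy_difference | charge | geometry_item
# structure_ids: comma-separated ids; energy_difference entries list exactly
#   two (distorted,equilibrium).
# detail: kind-specific; atom index for charge entries, dash-joined atom
#   indices for geometry items, empty otherwise.

TRAINSET_KINDS <- c("energy_difference", "charge", "geometry_item")

#' Assemble a training set object
#'
#' @param entries Data frame/tibble with columns `id`, `kind`,
#'   `structure_ids` (comma-separated structure ids), `detail`, `reference`,
#'   `weight`, `partition` (`"train"` or `"validation"`).
#' @param structures Named list of [reax_structure] objects; every id
#'   referenced by `entries` must be present.
#' @return An object of class `reax_trainset`.
#' @export
reax_trainset <- function(entries, structures) {
  entries <- tibble::as_tibble(entries)
  if (!"detail" %in% names(entries)) entries$detail <- ""
  entries$detail[is.na(entries$detail)] <- ""
  needed <- c("id", "kind", "structure_ids", "reference", "weight", "partition")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols) > 0) {
    stop("training set is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  ts <- structure(
    list(entries = entries[, c(
      "id", "kind", "structure_ids", "detail",
      "reference", "weight", "partition"
    )], structures = structures),
    class = "reax_trainset"
  )
  validate_trainset(ts)
  ts
}

entry_structure_ids <- function(sid) strsplit(sid, ",", fixed = TRUE)[[1]]

#' Validate a training set
#'
#' Checks entry kinds, positive weights, partition labels, structure
#' references, and that energy-difference entries reference exactly two
#' structures.
#'
#' @param ts A [reax_trainset].
#' @return `ts`, invisibly.
#' @export
validate_trainset <- function(ts) {
  e <- ts$entries
  bad_kind <- setdiff(unique(e$kind), TRAINSET_KINDS)
  if (length(bad_kind) > 0) {
    stop("unknown entry kind(s): ", paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(e$weight)) || any(e$weight <= 0)) {
    stop("entry weights must be positive", call. = FALSE)
  }
  bad_part <- setdiff(unique(e$partition), c("train", "validation"))
  if (length(bad_part) > 0) {
    stop("unknown partition label(s): ", paste(bad_part, collapse = ", "),
      call. = FALSE
    )
  }
  for (k in seq_len(nrow(e))) {
    ids <- entry_structure_ids(e$structure_ids[k])
    missing_ids <- setdiff(ids, names(ts$structures))
    if (length(missing_ids) > 0) {
      stop("entry '", e$id[k], "' references missing structure id(s): ",
        paste(missing_ids, collapse = ", "),
        call. = FALSE
      )
    }
    if (e$kind[k] == "energy_difference" && length(ids) != 2) {
      stop("energy_difference entry '", e$id[k],
        "' must reference exactly two structures (distorted,equilibrium)",
        call. = FALSE
      )
    }
    if (e$kind[k] == "charge" && !grepl("^[0-9]+$", e$detail[k])) {
      stop("charge entry '", e$id[k], "' needs an atom index in `detail`",
        call. = FALSE
      )
    }
  }
  invisible(ts)
}

#' @export
print.reax_trainset <- function(x, ...) {
  e <- x$entries
  cat(
    "<reax_trainset> ", nrow(e), " entries (",
    sum(e$partition == "train"), " train / ",
    sum(e$partition == "validation"), " validation), ",
    length(x$structures), " structures\n",
    sep = ""
  )
  print(table(e$kind))
  invisible(x)
}

#' Read a training set from TSV (plus a structure library)
#'
#' @param path Path to a tab-separated training-set file (see the package
#'   vignette for the schema).
#' @param structures Named list of [reax_structure] objects resolving the
#'   ids referenced in the file, or the path of a multi-frame extended-XYZ
#'   file whose frame comments carry `id=` annotations.
#' @return A [reax_trainset].
#' @export
read_trainset <- function(path, structures) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path,
    sep = "\t", stringsAsFactors = FALSE,
    colClasses = c(
      id = "character", kind = "character", structure_ids = "character",
      detail = "character", reference = "numeric", weight = "numeric",
      partition = "character"
    )
  )
  if (is.character(structures) && length(structures) == 1L) {
    frames <- read_structure_file(structures)
    ids <- vapply(frames, function(f) {
      ann <- parse_extxyz_comment(f$comment)
      if (is.null(ann$id)) stop("structure library frame lacks an id= annotation", call. = FALSE)
      ann$id
    }, "")
    names(frames) <- ids
    structures <- frames
  }
  reax_trainset(df, structures)
}

#' Write a training set to TSV (and optionally its structures)
#'
#' @param ts A [reax_trainset].
#' @param path Output TSV path.
#' @param structures_path Optional path; when given, the structure library is
#'   written as multi-frame extended XYZ with `id=` comment annotations.
#' @return `path`, invisibly.
#' @export
write_trainset <- function(ts, path, structures_path = NULL) {
  utils::write.table(ts$entries, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  if (!is.null(structures_path)) {
    frames <- ts$structures
    lines <- unlist(lapply(names(frames), function(id) {
      s <- frames[[id]]
      format_xyz_frame(s, comment = paste(structure_comment(s), sprintf("id=%s", id)))
    }))
    writeLines(lines, structures_path)
  }
  invisible(path)
}
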