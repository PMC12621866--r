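# Shared readers/writers and configuration.

#' Read a FASTA file into sequence records
#'
#' @param path FASTA file (any line wrapping; CRLF tolerated).
#' @return `data.frame` with columns `id`, `description` (text after the
#'   first space in the header, `""` if none), `sequence`, `source`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  data.frame(id = id, description = description,
             sequence = as.character(set), source = "fasta",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA
#'
#' Sequences are wrapped at 80 columns. When the records carry a `"params"`
#' attribute (as engine output does), the decoding parameters are encoded
#' in each description line as `key=value` pairs.
#'
#' @param records Sequence-record `data.frame`.
#' @param path Output file.
#' @export
write_fasta <- function(records, path) {
  desc <- records$description
  params <- attr(records, "params")
  if (!is.null(params) && inherits(params, "fc_sampling_params")) {
    tag <- paste0("T=", params$temperature,
                  " top_k=", if (is.null(params$top_k)) "all" else params$top_k,
                  " top_p=", params$top_p,
                  " rep_penalty=", params$repetition_penalty,
                  " max_tokens=", params$max_tokens,
                  " max_residues=", params$max_residues)
    desc <- ifelse(nzchar(desc), paste(desc, tag), tag)
  }
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- trimws(paste(records$id, desc))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read heavy-atom records from a PDB file
#'
#' Parses `ATOM` records of the first model via `bio3d`, keeping altloc
#' blank or `'A'` and dropping hydrogens. The element symbol is taken from
#' the element column with a fallback to the first letter of the atom name;
#' van der Waals radii are attached via [vdw_radius()].
#'
#' @param path PDB file.
#' @return `data.frame` with columns `residue_index` (1-based ordinal over
#'   residues in file order), `residue_name`, `element`, `x`, `y`, `z`,
#'   `radius`.
#' @export
read_pdb_atoms <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) {
    warning("no ATOM records in ", path)
    return(data.frame(residue_index = integer(0), residue_name = character(0),
                      element = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), radius = numeric(0),
                      stringsAsFactors = FALSE))
  }
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  elem <- toupper(ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                         substr(gsub("[^A-Za-z].*$", "", at$elety), 1L, 1L),
                         at$elesy))
  keep <- !elem %in% c("H", "D")
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  res_key <- paste(at$chain, at$resno, at$insert)
  data.frame(residue_index = as.integer(factor(res_key, levels = unique(res_key))),
             residue_name = at$resid,
             element = elem,
             x = at$x, y = at$y, z = at$z,
             radius = vdw_radius(elem),
             stringsAsFactors = FALSE)
}

# --- TSV dialect: tab-separated, '#'-prefixed header line, UTF-8, '.'
# decimal separator. ---

write_tsv_hash <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0L) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# Read a headerless (or '#'-headed) TSV into character columns; returns an
# empty data.frame for empty files.
read_tsv_table <- function(path, min_cols = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(data.frame())
  out <- utils::read.delim(text = lines, header = FALSE, sep = "\t",
                           quote = "", comment.char = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(out) < min_cols) {
    stop(path, ": expected at least ", min_cols, " tab-separated columns, got ",
         ncol(out))
  }
  out
}

# Write m8-dialect homology hits (no header; plain 12-column TSV).
write_m8 <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML configuration with the recognized top-level sections `filter`,
#' `annotation`, `sasa`, `escape`, `grid`, `planted`, `seed`, `paths`,
#' `columns`. Unknown keys are rejected so typos cannot silently change an
#' analysis.
#'
#' @param path YAML file.
#' @return Named list of configuration sections.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("filter", "annotation", "sasa", "escape", "grid", "planted",
             "seed", "paths", "columns")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}
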