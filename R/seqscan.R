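#' Read a protein FASTA file
#'
#' Parses a (optionally gzip-compressed) protein FASTA file into a data frame
#' of protein records. The record identifier is the first whitespace-delimited
#' token of the header; the remainder of the header is kept as the
#' description. Multi-line sequences are concatenated and record order is
#' preserved.
#'
#' @param path Path to a FASTA file (`.faa`, `.fasta`, optionally `.gz`).
#' @return A data frame with columns `id`, `description` and `sequence`
#'   (amino-acid one-letter codes, as read).
#' @examples
#' faa <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 a protein", "CAA", "CH"), faa)
#' read_fasta(faa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) > 0L && !startsWith(first[[1L]], ">") &&
      !startsWith(first[[1L]], ";")) {
    stop("Malformed FASTA (sequence data before any '>' header): ", path,
         call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    return(data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  headers <- names(aa)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[[`, character(1L), 1L)
  desc <- sub("^\\S+[ \t]*", "", headers)
  data.frame(id = ids, description = desc,
             sequence = as.character(aa), stringsAsFactors = FALSE)
}

#' Locate C-X-X-C-H heme-binding motifs in a protein sequence
#'
#' Scans every window of length five for the c-type cytochrome heme-binding
#' signature C-X-X-C-H: cysteine, any two residues, cysteine, histidine.
#' Matching is case-insensitive and purely positional: the two X positions
#' accept any residue symbol, including ambiguity codes, but neither a stop
#' (`*`) nor a gap (`-`) may occupy any of the five positions. Overlapping
#' occurrences are all reported.
#'
#' @param sequence A single residue string.
#' @return Integer vector of 0-based start positions, sorted ascending.
#'   Sequences shorter than five residues yield an empty vector.
#' @examples
#' scan_heme_motifs("CAACH")     # 0
#' scan_heme_motifs("CAACHACH")  # 0, 3 (overlap allowed)
#' @export
scan_heme_motifs <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 5L) return(integer(0))
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- ch == "*" | ch == "-"
  i <- seq_len(n - 4L)
  hit <- ch[i] == "C" & ch[i + 3L] == "C" & ch[i + 4L] == "H" &
    !(bad[i] | bad[i + 1L] | bad[i + 2L] | bad[i + 3L] | bad[i + 4L])
  which(hit) - 1L
}

#' Census multiheme cytochromes in a proteome
#'
#' Counts C-X-X-C-H heme-binding motifs in every protein of a proteome and
#' classifies as multiheme cytochromes (MHC) the proteins carrying at least
#' `min_motifs` motifs. The motif total `n_motifs_in_mhc` is summed over
#' MHC-classified proteins only, i.e. the motifs "carried by" the MHC set.
#'
#' @param records Data frame of protein records as returned by [read_fasta()].
#' @param min_motifs Minimum motif count for a protein to qualify as an MHC
#'   (default 2, the operational multiheme threshold).
#' @param genome_id Identifier recorded in the summary (e.g. an assembly
#'   accession).
#' @return An object of class `proteome_summary`: a list with `genome_id`,
#'   `n_proteins`, `n_mhc`, `n_motifs_in_mhc` and `per_protein`, a data frame
#'   with columns `protein_id`, `n_motifs`, `is_mhc` (one row per protein, in
#'   input order).
#' @examples
#' recs <- data.frame(id = c("p1", "p2"), description = "",
#'                    sequence = c("CAACHMCAACH", "CAACH"))
#' classify_proteome(recs, min_motifs = 2, genome_id = "demo")
#' @export
classify_proteome <- function(records, min_motifs = 2L, genome_id = "genome") {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  if (min_motifs < 1L) stop("min_motifs must be >= 1", call. = FALSE)
  dup <- records$id[duplicated(records$id)]
  if (length(dup) > 0L) {
    stop("Duplicate protein id(s) in proteome: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  n_motifs <- vapply(records$sequence,
                     function(s) length(scan_heme_motifs(s)), integer(1L),
                     USE.NAMES = FALSE)
  is_mhc <- n_motifs >= min_motifs
  out <- list(
    genome_id = genome_id,
    n_proteins = nrow(records),
    n_mhc = sum(is_mhc),
    n_motifs_in_mhc = sum(n_motifs[is_mhc]),
    min_motifs = as.integer(min_motifs),
    per_protein = data.frame(protein_id = records$id,
                             n_motifs = n_motifs,
                             is_mhc = is_mhc,
                             stringsAsFactors = FALSE)
  )
  class(out) <- "proteome_summary"
  out
}

#' @export
print.proteome_summary <- function(x, ...) {
  cat("Proteome MHC census for", x$genome_id, "\n")
  cat("  proteins scanned :", x$n_proteins, "\n")
  cat(sprintf("  MHC (>= %d motifs): %d\n", x$min_motifs, x$n_mhc))
  cat("  motifs in MHCs   :", x$n_motifs_in_mhc, "\n")
  invisible(x)
}

#' Write MHC census tables
#'
#' Writes the per-protein motif table and the one-row proteome summary as
#' tab-separated files.
#'
#' @param summary A `proteome_summary` from [classify_proteome()].
#' @param per_protein_path,summary_path Output TSV paths; either may be `NULL`
#'   to skip that table.
#' @return Invisibly, the summary.
#' @export
write_mhc_tables <- function(summary, per_protein_path = NULL,
                             summary_path = NULL) {
  stopifnot(inherits(summary, "proteome_summary"))
  if (!is.null(per_protein_path)) {
    tab <- cbind(genome_id = summary$genome_id, summary$per_protein)
    write_tsv_table(tab, per_protein_path)
  }
  if (!is.null(summary_path)) {
    tab <- data.frame(genome_id = summary$genome_id,
                      n_proteins = summary$n_proteins,
                      n_mhc = summary$n_mhc,
                      n_motifs_in_mhc = summary$n_motifs_in_mhc)
    write_tsv_table(tab, summary_path)
  }
  invisible(summary)
}
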