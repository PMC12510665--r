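#' @importFrom stats rnorm runif setNames sd median quantile uniroot rbinom
#' @importFrom utils read.delim write.table head tail
NULL

PROTEIN_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
RNA_ALPHABET <- c("A", "C", "G", "U")

#' Create a validated sequence record
#'
#' A sequence record holds an identifier, a sequence string and its kind
#' (`"protein"` or `"rna"`). Protein sequences must use the 20 standard
#' amino-acid letters; RNA sequences must use A/C/G/U. DNA-style `T` is
#' accepted on input for RNA and silently canonicalized to `U`; any other
#' character is rejected.
#'
#' @param id Identifier string.
#' @param seq Sequence string (non-empty).
#' @param kind Either `"protein"` or `"rna"`.
#' @return A list of class `seq_record` with fields `id`, `seq`, `kind`.
#' @export
sequence_record <- function(id, seq, kind = c("protein", "rna")) {
  kind <- match.arg(kind)
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("sequence for '", id, "' must be a non-empty string")
  seq <- toupper(seq)
  if (kind == "rna") seq <- gsub("T", "U", seq, fixed = TRUE)
  alph <- if (kind == "protein") PROTEIN_ALPHABET else RNA_ALPHABET
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), alph)
  if (length(bad))
    stop("sequence '", id, "' contains characters outside the ", kind,
         " alphabet: ", paste(bad, collapse = ", "))
  structure(list(id = id, seq = seq, kind = kind), class = "seq_record")
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param kind `"protein"` or `"rna"`; all records are validated against the
#'   corresponding alphabet (with T mapped to U for RNA).
#' @return A list of [sequence_record()] objects, in file order.
#' @export
read_fasta <- function(path, kind = c("protein", "rna")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in '", path,
                                           "': ", conditionMessage(e)))
  ids <- names(set)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("FASTA format error in '", path, "': empty or missing header")
  w <- Biostrings::width(set)
  if (any(w == 0L))
    stop("FASTA format error in '", path, "': empty sequence for '",
         ids[which(w == 0L)[1L]], "'")
  lapply(seq_along(set),
         function(i) sequence_record(ids[i], as.character(set[[i]]), kind))
}

#' Write sequence records to FASTA
#'
#' @param records List of [sequence_record()] objects (or named character).
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records))
    records <- lapply(names(records),
                      function(id) list(id = id, seq = records[[id]]))
  seqs <- vapply(records, `[[`, "", "seq")
  ids <- vapply(records, `[[`, "", "id")
  set <- Biostrings::BStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Create a protein-RNA interaction record
#'
#' @param protein,rna [sequence_record()] objects of the matching kind.
#' @param source_tag Free-text provenance tag.
#' @param weight Sampling weight in (0, 1], or `NA` when not yet assigned.
#' @param complex_cluster_id Integer complex-cluster key, or `NA` when unset.
#' @return A list of class `interaction_record`.
#' @export
interaction_record <- function(protein, rna, source_tag = "",
                               weight = NA_real_,
                               complex_cluster_id = NA_integer_) {
  stopifnot(inherits(protein, "seq_record"), inherits(rna, "seq_record"))
  if (protein$kind != "protein" || rna$kind != "rna")
    stop("interaction_record needs a protein record and an rna record")
  if (!is.na(weight) && (weight <= 0 || weight > 1))
    stop("weight must lie in (0, 1]")
  structure(list(protein = protein, rna = rna, source_tag = source_tag,
                 weight = weight,
                 complex_cluster_id = as.integer(complex_cluster_id)),
            class = "interaction_record")
}

#' Read a protein-RNA interaction table
#'
#' Expects a TSV with header columns `protein_id`, `protein_seq`, `rna_id`,
#' `rna_seq`, `source_tag` (the last may be absent). Weights are left unset.
#'
#' @param path Path to the TSV file.
#' @return List of [interaction_record()] objects in file order.
#' @export
read_interaction_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("protein_id", "protein_seq", "rna_id", "rna_seq")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("interaction table '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!"source_tag" %in% names(df)) df$source_tag <- ""
  lapply(seq_len(nrow(df)), function(i) {
    interaction_record(
      sequence_record(df$protein_id[i], df$protein_seq[i], "protein"),
      sequence_record(df$rna_id[i], df$rna_seq[i], "rna"),
      source_tag = df$source_tag[i])
  })
}

#' Write interaction records as a TSV table
#'
#' @param records List of [interaction_record()] objects.
#' @param path Output path.
#' @export
write_interaction_table <- function(records, path) {
  df <- data.frame(
    protein_id = vapply(records, function(r) r$protein$id, ""),
    protein_seq = vapply(records, function(r) r$protein$seq, ""),
    rna_id = vapply(records, function(r) r$rna$id, ""),
    rna_seq = vapply(records, function(r) r$rna$seq, ""),
    source_tag = vapply(records, function(r) r$source_tag, ""),
    weight = vapply(records, function(r) r$weight, 0),
    complex_cluster_id = vapply(records, function(r) r$complex_cluster_id, 0L),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read protein domain annotations
#'
#' TSV with columns `protein_id`, `start`, `end`, `name`; intervals are
#' 1-based and inclusive on both ends (UniProt convention).
#'
#' @param path Path to the TSV file.
#' @return data.frame with the four columns, validated.
#' @export
read_domains <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end", "name")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("domain table '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(df$start < 1L | df$start > df$end)
  if (length(bad))
    stop("domain table '", path, "': invalid interval on row ", bad[1L],
         " (need 1 <= start <= end)")
  df[need]
}

#' Read a per-frame component-energy table
#'
#' TSV with columns `e_complex`, `e_protein`, `e_rna` (kJ/mol), one row per
#' trajectory frame.
#'
#' @param path Path to the TSV file.
#' @return data.frame with the three numeric columns.
#' @export
read_energy_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("e_complex", "e_protein", "e_rna")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("energy table '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  for (cl in need) df[[cl]] <- as.numeric(df[[cl]])
  if (anyNA(df[need])) stop("energy table '", path, "' has non-numeric entries")
  df[need]
}

PROTEIN_RESNAMES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                      "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                      "THR", "TRP", "TYR", "VAL", "HID", "HIE", "HIP", "CYX",
                      "ASH", "GLH", "LYN")
RNA_RESNAMES <- c("A", "C", "G", "U", "RA", "RC", "RG", "RU",
                  "A3", "C3", "G3", "U3", "A5", "C5", "G5", "U5")

ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.973762, S = 32.06)

infer_element <- function(name) {
  stripped <- gsub("[^A-Za-z]", "", name)
  el <- toupper(substr(stripped, 1L, 1L))
  el[el == ""] <- NA_character_
  el
}

chain_tag_from_resname <- function(resname) {
  tag <- rep(NA_character_, length(resname))
  tag[toupper(resname) %in% PROTEIN_RESNAMES] <- "protein"
  tag[toupper(resname) %in% RNA_RESNAMES] <- "rna"
  if (anyNA(tag))
    stop("cannot assign protein/rna chain tag for residue name(s): ",
         paste(unique(resname[is.na(tag)]), collapse = ", "))
  tag
}

new_trajectory <- function(atoms, frames) {
  stopifnot(is.data.frame(atoms), is.list(frames), length(frames) >= 1L)
  n <- nrow(atoms)
  for (f in frames) {
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3L)
      stop("every frame must be an n_atoms x 3 coordinate matrix")
    if (!all(is.finite(f))) stop("trajectory coordinates must be finite")
  }
  structure(list(atoms = atoms, frames = frames,
                 frame_count = length(frames)),
            class = "rna_trajectory")
}

#' Read a multi-model PDB file as a trajectory
#'
#' Models (MODEL/ENDMDL blocks) become frames, in file order. Chains are
#' tagged `protein` or `rna` from residue names (standard amino acids versus
#' A/C/G/U nucleotides); the element is inferred from the atom name when the
#' element column is absent. Coordinates are in Angstrom.
#'
#' @param path Path to a PDB file.
#' @return An object of class `rna_trajectory` with fields `atoms`
#'   (data.frame: name, element, chain_tag, mass, resname, resid), `frames`
#'   (list of n_atoms x 3 matrices) and `frame_count`.
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  model_starts <- grepl("^MODEL", lines)
  atom_lines <- grepl("^(ATOM|HETATM)", lines)
  if (any(model_starts)) {
    blk <- cumsum(model_starts)
    counts <- table(blk[atom_lines & blk > 0L])
    if (length(unique(as.integer(counts))) > 1L)
      stop("PDB format error in '", path,
           "': models have differing atom counts (",
           paste(as.integer(counts), collapse = ", "), ")")
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB format error in '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == ""))
    element <- infer_element(at$elety)
  element <- ifelse(is.na(element) | element == "",
                    infer_element(at$elety), toupper(trimws(element)))
  unknown <- setdiff(unique(element), names(ATOMIC_MASSES))
  if (length(unknown))
    stop("unknown element(s) in '", path, "': ",
         paste(unknown, collapse = ", "))
  atoms <- data.frame(
    name = at$elety,
    element = element,
    chain_tag = chain_tag_from_resname(at$resid),
    mass = unname(ATOMIC_MASSES[element]),
    resname = at$resid,
    resid = at$resno,
    stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  new_trajectory(atoms, frames)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj An `rna_trajectory` object.
#' @param path Output path.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "rna_trajectory"))
  at <- traj$atoms
  chain <- ifelse(at$chain_tag == "protein", "A", "B")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$frames[[f]]
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)), substr(at$name, 1L, 4L), substr(at$resname, 1L, 3L),
      chain, at$resid, xyz[, 1L], xyz[, 2L], xyz[, 3L], at$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
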