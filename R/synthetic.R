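# Synthetic-data generators. These define the study conditions for every
# test surface in the package: planted deterministic protein-motif -> RNA-word
# binding codes (so mapping recovery is checkable), cluster-structured
# sequence redundancy (exercising the identity-clustering thresholds), rigid
# toy trajectories with planted hydrogen-bond/contact geometry, and
# attention tensors with planted domain enrichment. Every generator is a
# pure function of its seed.

random_string <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Create a planted protein-motif to RNA-word binding code
#'
#' Draws `n_motifs` distinct protein motif words and as many distinct RNA
#' words, with a deterministic bijection motif -> word. Motifs are pairwise
#' distinct and none is a substring of another, so plantings are
#' unambiguous.
#'
#' @param n_motifs Number of motif/word pairs (default 4).
#' @param motif_len Protein motif length in residues (default 3).
#' @param word_len RNA word length in bases (default 5).
#' @param noise_rate Per-base corruption probability applied when sampling
#'   interactions (default 0, fully deterministic code).
#' @param seed RNG seed.
#' @return A list of class `motif_code` with `motifs`, `words`, `mapping`
#'   (named character: motif -> word), `noise_rate`, `seed`.
#' @export
make_motif_code <- function(n_motifs = 4L, motif_len = 3L, word_len = 5L,
                            noise_rate = 0, seed = 1L) {
  stopifnot(noise_rate >= 0, noise_rate < 1)
  if (n_motifs > length(PROTEIN_ALPHABET)^motif_len)
    stop("cannot draw ", n_motifs, " distinct motifs of length ", motif_len)
  if (n_motifs > length(RNA_ALPHABET)^word_len)
    stop("cannot draw ", n_motifs, " distinct RNA words of length ", word_len)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draw_distinct <- function(n, len, alphabet) {
    out <- character()
    tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 1000L * n) stop("could not draw distinct words")
      w <- random_string(len, alphabet)
      clash <- any(vapply(out, function(o)
        grepl(w, o, fixed = TRUE) || grepl(o, w, fixed = TRUE), TRUE))
      if (!clash) out <- c(out, w)
    }
    out
  }
  motifs <- draw_distinct(n_motifs, motif_len, PROTEIN_ALPHABET)
  words <- draw_distinct(n_motifs, word_len, RNA_ALPHABET)
  structure(list(motifs = motifs, words = words,
                 mapping = setNames(words, motifs),
                 noise_rate = noise_rate, seed = seed),
            class = "motif_code")
}

scrub_spurious_motifs <- function(chars, motifs, planted_at, motif_len,
                                  alphabet) {
  # mutate background positions until no motif occurs outside its planting
  protected <- unlist(lapply(planted_at, function(s) s:(s + motif_len - 1L)))
  seqstr <- paste(chars, collapse = "")
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 200L) stop("could not scrub spurious motif occurrences")
    bad <- NULL
    for (m in motifs) {
      g <- gregexpr(paste0("(?=", m, ")"), seqstr, perl = TRUE)[[1L]]
      if (g[1L] == -1L) next
      spurious <- setdiff(as.integer(g), planted_at)
      if (length(spurious)) { bad <- spurious[1L]; break }
    }
    if (is.null(bad)) return(strsplit(seqstr, "", fixed = TRUE)[[1L]])
    pos <- setdiff(bad:(bad + motif_len - 1L), protected)[1L]
    if (is.na(pos)) pos <- bad  # overlap with a planting: mutate the start
    chars <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
    chars[pos] <- sample(setdiff(alphabet, chars[pos]), 1L)
    seqstr <- paste(chars, collapse = "")
  }
}

#' Sample interaction records under a planted binding code
#'
#' Each protein is random background with 1 to `motifs_per_protein` distinct
#' motifs planted at random non-overlapping positions (background is
#' scrubbed of accidental motif occurrences so the code is unambiguous);
#' the paired RNA is the concatenation of the mapped words in motif order,
#' with each base independently corrupted with probability
#' `code$noise_rate`. Deterministic per seed.
#'
#' @param code A [make_motif_code()] object.
#' @param n Number of interaction records.
#' @param protein_len_range Length-2 integer range for protein lengths.
#' @param motifs_per_protein Maximum motifs planted per protein.
#' @param seed RNG seed.
#' @return List of [interaction_record()] objects; each carries attributes
#'   `motifs` (planted motifs, in positional order) and `true_rna` (the
#'   uncorrupted mapped RNA).
#' @export
sample_interactions <- function(code, n, protein_len_range = c(20L, 40L),
                                motifs_per_protein = 2L, seed = 1L) {
  stopifnot(inherits(code, "motif_code"), n >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  motif_len <- nchar(code$motifs[1L])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(protein_len_range[1L]:protein_len_range[2L], 1L)
    k <- sample.int(motifs_per_protein, 1L)
    chosen <- sample(code$motifs, k)
    # non-overlapping start positions
    starts <- integer()
    guard <- 0L
    while (length(starts) < k) {
      guard <- guard + 1L
      if (guard > 1000L) stop("protein too short for the requested motifs")
      cand <- sample.int(len - motif_len + 1L, 1L)
      if (!any(abs(cand - starts) < motif_len)) starts <- c(starts, cand)
    }
    ord <- order(starts)
    starts <- starts[ord]; chosen <- chosen[ord]
    chars <- sample(PROTEIN_ALPHABET, len, replace = TRUE)
    for (j in seq_len(k)) {
      idx <- starts[j]:(starts[j] + motif_len - 1L)
      chars[idx] <- strsplit(chosen[j], "", fixed = TRUE)[[1L]]
    }
    chars <- scrub_spurious_motifs(chars, code$motifs, starts, motif_len,
                                   PROTEIN_ALPHABET)
    true_rna <- paste(code$mapping[chosen], collapse = "")
    rna <- strsplit(true_rna, "", fixed = TRUE)[[1L]]
    if (code$noise_rate > 0) {
      flip <- runif(length(rna)) < code$noise_rate
      rna[flip] <- vapply(rna[flip], function(b)
        sample(setdiff(RNA_ALPHABET, b), 1L), "")
    }
    rec <- interaction_record(
      sequence_record(sprintf("P%05d", i), paste(chars, collapse = ""),
                      "protein"),
      sequence_record(sprintf("R%05d", i), paste(rna, collapse = ""), "rna"),
      source_tag = "synthetic")
    attr(rec, "motifs") <- chosen
    attr(rec, "true_rna") <- true_rna
    out[[i]] <- rec
  }
  out
}

#' Generate redundancy-structured sequence families
#'
#' Each family is a random founder plus mutated copies whose realized
#' identity to the founder (matches / length, equal-length substitutions
#' only) is within 3 percentage points of `target_identity`. Exercises the
#' identity-clustering thresholds: at 95% internal identity, clustering at
#' 0.9 recovers the families exactly; at 50% it shatters them.
#'
#' @param n_families Number of families.
#' @param members_per_family Members per family (founder included).
#' @param target_identity Within-family identity target in (0, 1).
#' @param seq_len Sequence length (default 60).
#' @param kind `"rna"` (default) or `"protein"`.
#' @param seed RNG seed.
#' @return Named character vector of sequences with a `family` attribute
#'   (integer labels).
#' @export
make_redundant_families <- function(n_families, members_per_family,
                                    target_identity, seq_len = 60L,
                                    kind = c("rna", "protein"), seed = 1L) {
  stopifnot(target_identity > 0, target_identity < 1)
  kind <- match.arg(kind)
  alphabet <- if (kind == "rna") RNA_ALPHABET else PROTEIN_ALPHABET
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_sub <- round((1 - target_identity) * seq_len)
  seqs <- character(); fam <- integer()
  for (f in seq_len(n_families)) {
    founder <- random_string(seq_len, alphabet)
    seqs <- c(seqs, founder); fam <- c(fam, f)
    for (m in seq_len(members_per_family - 1L)) {
      chars <- strsplit(founder, "", fixed = TRUE)[[1L]]
      pos <- sample.int(seq_len, n_sub)
      chars[pos] <- vapply(chars[pos], function(b)
        sample(setdiff(alphabet, b), 1L), "")
      seqs <- c(seqs, paste(chars, collapse = ""))
      fam <- c(fam, f)
    }
  }
  names(seqs) <- sprintf("F%02dM%02d", fam,
                         unlist(lapply(table(fam), seq_len)))
  attr(seqs, "family") <- fam
  seqs
}

#' Build a rigid toy trajectory with planted interface geometry
#'
#' Two rigid bodies (protein-tagged and RNA-tagged atoms) whose interface
#' contains, by construction: `n_hbonds` donor-H-acceptor triples satisfying
#' both hydrogen-bond criteria (D-A 3.0 Angstrom, angle 180 degrees),
#' `n_bad_distance` triples failing only the 4.5 Angstrom distance cutoff,
#' and `n_bad_angle` triples failing only the 150-degree angle cutoff, plus
#' `n_extra_contacts` isolated cross-chain atom pairs 4.0 Angstrom apart.
#' Groups are spaced 25 Angstrom apart so they never interact. A rigid
#' whole-system translation of `drift_per_frame` Angstrom per frame gives a
#' linearly growing unsuperposed RMSD without altering any internal
#' geometry; optional Gaussian jitter perturbs every coordinate.
#' Per-frame component energies are synthesized so the binding energy
#' equals `delta_e` exactly.
#'
#' @param n_frames Number of frames (default 10).
#' @param n_hbonds Planted passing hydrogen bonds (default 3).
#' @param n_bad_distance,n_bad_angle Planted failing geometries (default 1).
#' @param n_extra_contacts Additional isolated contact pairs (default 2).
#' @param jitter_sd Per-coordinate Gaussian noise, Angstrom (default 0).
#' @param drift_per_frame Rigid translation per frame, Angstrom (default 0).
#' @param delta_e Planted binding-energy schedule, kJ/mol (scalar or
#'   per-frame vector; default -5).
#' @param seed RNG seed.
#' @return List with `trajectory` (`rna_trajectory`), `energies`
#'   (data.frame) and `planted` (expected hbond and contact counts).
#' @export
make_toy_trajectory <- function(n_frames = 10L, n_hbonds = 3L,
                                n_bad_distance = 1L, n_bad_angle = 1L,
                                n_extra_contacts = 2L, jitter_sd = 0,
                                drift_per_frame = 0, delta_e = -5,
                                seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  atoms <- list(); coords <- list()
  add_atom <- function(name, element, chain, x, y, z, resname, resid) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = name, element = element, chain_tag = chain,
      mass = unname(ATOMIC_MASSES[element]), resname = resname,
      resid = resid, stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- c(x, y, z)
  }
  resid <- 0L
  y <- 0
  for (k in seq_len(n_hbonds)) {
    resid <- resid + 1L
    add_atom("N", "N", "protein", 0, y, 0, "GLY", resid)
    add_atom("H", "H", "protein", 1.0, y, 0, "GLY", resid)
    add_atom("O", "O", "rna", 3.0, y, 0, "A", 100L + resid)
    y <- y + 25
  }
  for (k in seq_len(n_bad_distance)) {
    resid <- resid + 1L
    add_atom("N", "N", "protein", 0, y, 0, "GLY", resid)
    add_atom("H", "H", "protein", 1.0, y, 0, "GLY", resid)
    add_atom("O", "O", "rna", 6.0, y, 0, "A", 100L + resid)
    y <- y + 25
  }
  for (k in seq_len(n_bad_angle)) {
    resid <- resid + 1L
    add_atom("N", "N", "protein", 0, y, 0, "GLY", resid)
    add_atom("H", "H", "protein", 1.0, y, 0, "GLY", resid)
    add_atom("O", "O", "rna", 1.0, y + 2.5, 0, "A", 100L + resid)
    y <- y + 25
  }
  for (k in seq_len(n_extra_contacts)) {
    resid <- resid + 1L
    add_atom("CA", "C", "protein", 0, y, 0, "GLY", resid)
    add_atom("P", "P", "rna", 4.0, y, 0, "A", 100L + resid)
    y <- y + 25
  }
  # bulk body atoms well away from the interface groups
  for (k in 1:3) {
    resid <- resid + 1L
    add_atom("CA", "C", "protein", -60, y + k * 25, 0, "GLY", resid)
    add_atom("C4'", "C", "rna", 60, y + k * 25, 0, "A", 100L + resid)
  }
  atoms <- do.call(rbind, atoms)
  base <- do.call(rbind, coords)
  frames <- lapply(seq_len(n_frames), function(f) {
    xyz <- base
    xyz[, 3L] <- xyz[, 3L] + drift_per_frame * (f - 1L)
    if (jitter_sd > 0)
      xyz <- xyz + matrix(rnorm(length(xyz), sd = jitter_sd), nrow(xyz), 3L)
    xyz
  })
  traj <- new_trajectory(atoms, frames)
  de <- rep_len(delta_e, n_frames)
  energies <- data.frame(e_complex = -1500 + de,
                         e_protein = rep(-1000, n_frames),
                         e_rna = rep(-500, n_frames))
  # contacts per passing hbond: N-O (3.0) and H-O (2.0); per bad-angle:
  # N-O (2.69) and H-O (2.5); bad-distance groups contribute none.
  planted <- list(hbonds = n_hbonds,
                  contacts = 2L * n_hbonds + 2L * n_bad_angle +
                    n_extra_contacts,
                  delta_e = de)
  list(trajectory = traj, energies = energies, planted = planted)
}

#' Build an attention tensor with planted domain enrichment
#'
#' Pre-normalization weight for a protein position is 1 (plus uniform noise)
#' outside the domains and `enrichment` times that inside; each
#' (layer, head, rna_position) row is then normalized. With `noise = 0` and
#' single-residue tokens the resulting attention ratio is exactly
#' `enrichment`.
#'
#' @param protein_len Number of protein tokens/residues.
#' @param domains data.frame with `start`, `end` (1-based inclusive).
#' @param enrichment In-domain multiplier (>= 1).
#' @param noise Uniform noise amplitude on the pre-normalization weights.
#' @param n_layers,n_heads,n_rna Tensor dimensions.
#' @param seed RNG seed.
#' @return An [attention_tensor()].
#' @export
make_attention_fixture <- function(protein_len, domains, enrichment = 2,
                                   noise = 0, n_layers = 2L, n_heads = 4L,
                                   n_rna = 10L, seed = 1L) {
  stopifnot(enrichment >= 1, noise >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  inside <- domain_mask(domains, protein_len)
  w <- array(0, dim = c(n_layers, n_heads, n_rna, protein_len))
  for (l in seq_len(n_layers))
    for (h in seq_len(n_heads))
      for (r in seq_len(n_rna)) {
        row <- 1 + noise * runif(protein_len)
        row[inside] <- row[inside] * enrichment
        w[l, h, r, ] <- row / sum(row)
      }
  attention_tensor(w)
}
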