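#' Synthetic pMHC generator configuration
#'
#' The stated world of the desk-scale generator: a polymorphic allele panel
#' derived from one ancestral sequence by seeded point substitutions,
#' chain-like 3D structures from a self-avoiding random walk with
#' peptide-bond-scale steps (3.8 Angstrom), peptides of length 8-12, and
#' IC50 values from a planted anchor/pocket BLOSUM50 rule whose noise
#' level sets an SRCC signal ceiling of about 0.8 (`noise_sd = 0.5`,
#' calibrated empirically: the rank correlation between the clean
#' planted score and the noisy affinity is ~0.79 at the default scale).
#'
#' @param n_alleles alleles in the panel
#' @param mutations_per_allele distinct substituted sites per allele
#' @param mhc_length residues per MHC (<= 300; default 60 keeps desk-scale
#'   CPU budgets while preserving the length >> peptide regime)
#' @param n_peptides distinct peptides (each paired with every allele)
#' @param peptide_length_range inclusive length range, within 8-12
#' @param n_pseudo_positions binding-site positions
#' @param n_anchors peptide anchor positions carrying the planted signal
#' @param bond_length walk step in Angstrom
#' @param contact_density_range acceptable 8-Angstrom contact density
#' @param noise_sd Gaussian noise on the planted latent score
#' @param structure_coupling weight of the structure-coupled score term
#'   (contact-count modifier at pocket residues); 0 disables it
#' @param seed master seed
#' @export
synthetic_config <- function(n_alleles = 20L, mutations_per_allele = 8L,
                             mhc_length = 60L, n_peptides = 60L,
                             peptide_length_range = c(8L, 12L),
                             n_pseudo_positions = 16L, n_anchors = 3L,
                             bond_length = 3.8,
                             contact_density_range = c(0.02, 0.4),
                             noise_sd = 0.5, structure_coupling = 0,
                             seed = 1L) {
  stopifnot(n_alleles >= 1L, mhc_length >= 10L, mhc_length <= 300L,
            n_peptides >= 1L, bond_length > 0,
            peptide_length_range[1L] >= 8L, peptide_length_range[2L] <= 12L,
            n_anchors >= 1L, n_anchors <= 8L,
            n_pseudo_positions >= n_anchors,
            n_pseudo_positions <= mhc_length)
  as.list(environment())
}

#' Generate a polymorphic allele panel
#'
#' One ancestral random sequence; each allele substitutes
#' `mutations_per_allele` distinct sites with a different residue.
#' @param cfg [synthetic_config()]
#' @return list of MHC [sequence_record()]s named `allele01`, ...
#' @export
generate_alleles <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "alleles"), {
    ancestor <- sample(AA_ALPHABET, cfg$mhc_length, replace = TRUE)
    out <- vector("list", cfg$n_alleles)
    for (a in seq_len(cfg$n_alleles)) {
      s <- ancestor
      if (cfg$mutations_per_allele > 0L) {
        sites <- sample(cfg$mhc_length, cfg$mutations_per_allele)
        for (site in sites) {
          s[site] <- sample(setdiff(AA_ALPHABET, s[site]), 1L)
        }
      }
      id <- sprintf("allele%02d", a)
      out[[a]] <- sequence_record(id, paste(s, collapse = ""), "MHC")
    }
    names(out) <- vapply(out, `[[`, "", "id")
    attr(out, "ancestor") <- paste(ancestor, collapse = "")
    out
  })
}

# One self-avoiding walk attempt; NULL when it dead-ends.
.walk_once <- function(n, step, exclusion = 1.0, max_tries = 100L) {
  coords <- matrix(0, n, 3L)
  for (i in 2L:n) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      u <- stats::rnorm(3L)
      u <- u / sqrt(sum(u * u))
      cand <- coords[i - 1L, ] + step * u
      d2 <- rowSums((coords[seq_len(i - 1L), , drop = FALSE] -
                       matrix(cand, i - 1L, 3L, byrow = TRUE))^2)
      if (all(d2 > exclusion^2)) {
        coords[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  coords
}

#' Generate a chain-like 3D structure for a sequence
#'
#' Seeded self-avoiding random walk (step = bond length, excluded radius
#' 1 Angstrom), resampled until the 8-Angstrom contact density lands in
#' the configured range. A toy geometry, not protein-realistic.
#' @param seq sequence (sets the residue count)
#' @param cfg [synthetic_config()]
#' @param seed walk seed (default derives from cfg seed and the sequence)
#' @return `cmhs_atoms` data.frame of CA atoms
#' @export
generate_structure <- function(seq, cfg, seed = NULL) {
  n <- nchar(seq)
  if (is.null(seed)) seed <- derive_seed(cfg$seed, paste0("walk", seq))
  coords <- with_seed(seed, {
    for (attempt in 1:50) {
      co <- .walk_once(n, cfg$bond_length)
      if (is.null(co)) next
      A <- contact_adjacency(co, 8)
      dens <- sum(A) / (n * (n - 1))
      if (dens >= cfg$contact_density_range[1L] &&
          dens <= cfg$contact_density_range[2L]) break
      co <- NULL
    }
    if (is.null(co)) cmhs_stop("could not generate a self-avoiding walk",
                               "cmhs_structure_error")
    co
  })
  df <- data.frame(residue_index = seq_len(n), atom_name = "CA",
                   x = round(coords[, 1L], 3), y = round(coords[, 2L], 3),
                   z = round(coords[, 3L], 3), stringsAsFactors = FALSE)
  class(df) <- c("cmhs_atoms", "data.frame")
  df
}

#' Planted anchor/pocket binding rule
#'
#' Binding strength is a weighted sum of BLOSUM50 similarities between
#' fixed peptide anchor positions and fixed MHC pocket residues (a subset
#' of the pseudo-sequence). `center` and `scale` standardize the raw score
#' before the sigmoid; [make_dataset()] calibrates them on the generated
#' panel so the latent score is approximately standard normal.
#' @param pseudo_positions pseudo-sequence positions to draw pockets from
#' @param cfg [synthetic_config()]
#' @return object of class `cmhs_rule`: anchors, pockets, weights,
#'   center, scale
#' @export
planted_rule <- function(pseudo_positions, cfg) {
  with_seed(derive_seed(cfg$seed, "rule"), {
    anchors <- sort(sample(seq_len(cfg$peptide_length_range[1L]),
                           cfg$n_anchors))
    pockets <- sample(pseudo_positions, cfg$n_anchors)
    weights <- stats::runif(cfg$n_anchors, 0.5, 1.5)
    structure(list(anchors = anchors, pockets = pockets, weights = weights,
                   center = 0, scale = 1), class = "cmhs_rule")
  })
}

#' Raw planted score of a pair (pure function of the two sequences)
#' @param mhc_seq,peptide character sequences
#' @param rule `cmhs_rule`
#' @export
planted_score <- function(mhc_seq, peptide, rule) {
  bl <- blosum50_matrix()
  pep <- strsplit(toupper(peptide), "")[[1L]]
  mhc <- strsplit(toupper(mhc_seq), "")[[1L]]
  sum(rule$weights * bl[cbind(pep[rule$anchors], mhc[rule$pockets])])
}

#' Planted IC50 for a pMHC pair
#'
#' Latent affinity `a = plogis((score - center) / scale + noise)` with
#' seeded Gaussian noise, mapped to `ic50 = 50000^(1 - a)` so that
#' [normalize_ic50()] inverts the map exactly when noise is off.
#' @param mhc_seq,peptide sequences
#' @param rule `cmhs_rule` (calibrated)
#' @param noise_sd latent noise standard deviation
#' @param seed noise seed
#' @param extra additive latent term (e.g. the structure-coupled score)
#' @return ic50 in nM
#' @export
planted_affinity <- function(mhc_seq, peptide, rule, noise_sd = 0,
                             seed = 1L, extra = 0) {
  s <- (planted_score(mhc_seq, peptide, rule) - rule$center) / rule$scale
  z <- s + extra + if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(1L, sd = noise_sd))
  } else 0
  a <- stats::plogis(z)
  50000^(1 - a)
}

#' Generate a complete synthetic pMHC dataset
#'
#' Builds the allele panel, structures, pseudo-positions, peptides and
#' the all-pairs affinity table from the planted rule; optionally writes
#' the on-disk bundle (FASTA, PDB, pseudo-position list, affinity CSV and
#' a manifest recording the seed and ground-truth rule).
#'
#' When `structure_coupling > 0`, a per-allele term proportional to the
#' standardized 8-Angstrom contact counts of the pocket residues is added
#' to the latent score, making part of the signal reachable only through
#' the structure branch.
#'
#' @param cfg [synthetic_config()]
#' @param dir optional bundle output directory (created if missing)
#' @return `cmhs_dataset` with attributes `rule`, `manifest`
#' @export
make_dataset <- function(cfg = synthetic_config(), dir = NULL) {
  alleles <- generate_alleles(cfg)
  pseudo <- with_seed(derive_seed(cfg$seed, "pseudo"),
                      sort(sample(cfg$mhc_length, cfg$n_pseudo_positions)))
  rule <- planted_rule(pseudo, cfg)
  peptides <- with_seed(derive_seed(cfg$seed, "peptides"), {
    lens <- sample(seq(cfg$peptide_length_range[1L],
                       cfg$peptide_length_range[2L]),
                   cfg$n_peptides, replace = TRUE)
    vapply(lens, function(l) paste(sample(AA_ALPHABET, l, replace = TRUE),
                                   collapse = ""), "")
  })
  peptides <- unique(peptides)
  structures <- lapply(alleles, function(a) generate_structure(a$sequence,
                                                               cfg))
  coords <- lapply(structures, function(s) {
    m <- as.matrix(s[, c("x", "y", "z")])
    rownames(m) <- s$residue_index
    m
  })
  # structure-coupled term: standardized pocket contact counts per allele
  struct_term <- vapply(names(alleles), function(id) {
    A <- contact_adjacency(coords[[id]], 8)
    sum(rule$weights * rowSums(A)[rule$pockets])
  }, 0)
  if (stats::sd(struct_term) > 0) {
    struct_term <- (struct_term - mean(struct_term)) / stats::sd(struct_term)
  } else struct_term[] <- 0
  struct_term <- cfg$structure_coupling * struct_term

  pairs <- expand.grid(mhc_id = names(alleles), peptide = peptides,
                       stringsAsFactors = FALSE)
  raw <- mapply(function(m, p) planted_score(alleles[[m]]$sequence, p, rule),
                pairs$mhc_id, pairs$peptide)
  rule$center <- mean(raw)
  rule$scale <- max(stats::sd(raw), 1e-9)
  z <- (raw - rule$center) / rule$scale + struct_term[pairs$mhc_id]
  noise <- with_seed(derive_seed(cfg$seed, "icnoise"),
                     stats::rnorm(nrow(pairs), sd = cfg$noise_sd))
  affinity <- stats::plogis(z + noise)
  table <- data.frame(mhc_id = pairs$mhc_id, peptide = pairs$peptide,
                      ic50 = 50000^(1 - affinity),
                      stringsAsFactors = FALSE)
  table$affinity <- normalize_ic50(table$ic50)
  table$label <- binarize(table$ic50)
  ds <- cmhs_dataset(table,
                     vapply(alleles, `[[`, "", "sequence"),
                     coords, pseudo)
  manifest <- list(seed = cfg$seed, config = cfg[setdiff(names(cfg), "")],
                   rule = unclass(rule),
                   pseudo_positions = pseudo,
                   n_pairs = nrow(table),
                   label_balance = mean(table$label))
  attr(ds, "rule") <- rule
  attr(ds, "manifest") <- manifest
  if (!is.null(dir)) .write_bundle(ds, structures, alleles, manifest, dir)
  ds
}

.write_bundle <- function(ds, structures, alleles, manifest, dir) {
  dir.create(file.path(dir, "pdb"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(alleles, file.path(dir, "alleles.fasta"))
  peps <- unique(ds$table$peptide)
  write_fasta(mapply(function(p, i) sequence_record(sprintf("pep%03d", i),
                                                    p, "peptide"),
                     peps, seq_along(peps), SIMPLIFY = FALSE),
              file.path(dir, "peptides.fasta"))
  for (id in names(structures)) {
    write_pdb(structures[[id]], file.path(dir, "pdb", paste0(id, ".pdb")))
  }
  write_pseudo_positions(ds$pseudo_positions,
                         file.path(dir, "pseudo_positions.txt"))
  write_affinity_table(ds$table[, c("mhc_id", "peptide", "ic50")],
                       file.path(dir, "affinity.csv"))
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Load a synthetic bundle written by [make_dataset()]
#' @param dir bundle directory
#' @return `cmhs_dataset`
#' @export
read_dataset <- function(dir) {
  alleles <- read_fasta(file.path(dir, "alleles.fasta"), role = "MHC")
  names(alleles) <- vapply(alleles, `[[`, "", "id")
  coords <- lapply(names(alleles), function(id) {
    residue_coords(read_pdb(file.path(dir, "pdb", paste0(id, ".pdb"))))
  })
  names(coords) <- names(alleles)
  pseudo <- read_pseudo_positions(file.path(dir, "pseudo_positions.txt"))
  table <- read_affinity_table(file.path(dir, "affinity.csv"))
  cmhs_dataset(table, vapply(alleles, `[[`, "", "sequence"), coords, pseudo)
}
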