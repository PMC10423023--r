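# Synthetic benchmark generator: a bipartite block model in which compounds
# and sequences are assigned to latent groups, within-group pairs interact
# with probability p_in and cross-group pairs with p_out, and group identity
# is detectable from the raw inputs through group-specific substructure
# motifs (functional groups appended to a random alkane/ether backbone) and
# group-specific 6-mer sequence motifs. Congruent views built on this data
# therefore carry mutual information about group identity, which is exactly
# what contrastive pretraining is meant to exploit.

COMPOUND_MOTIFS <- c("C(=O)O",   # carboxylic acid
                     "C(=O)N",   # amide
                     "Cl",       # chloro
                     "S",        # thiol
                     "Br",       # bromo
                     "C#N",      # nitrile
                     "F",        # fluoro
                     "N")        # amine
COMPOUND_MOTIF_ATOMS <- c(3L, 3L, 1L, 1L, 1L, 2L, 1L, 1L)

SEQUENCE_MOTIFS <- c("WHKWHK", "CMYCMY", "DEDEDE", "FPFPFP",
                     "RNRNRN", "QGQGQG", "ILILIL", "TVTVTV")

#' Block-model configuration
#'
#' @param n_compounds,n_sequences entity counts.
#' @param n_groups number of latent groups `G` (at most 8, the number of
#'   distinct motifs; `G <= min(n_compounds, n_sequences)`).
#' @param p_in,p_out within-/cross-group interaction probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param motif_strength probability that a member's molecule/sequence embeds
#'   its group motif.
#' @param seq_length_range,mol_size_range inclusive ranges for sequence length
#'   (residues) and molecule size (heavy atoms).
#' @param seed master seed; the dataset is fully determined by it.
#' @return a `block_model_config` list.
#' @export
block_model_config <- function(n_compounds = 80L, n_sequences = 80L,
                               n_groups = 4L, p_in = 0.3, p_out = 0.01,
                               motif_strength = 0.9,
                               seq_length_range = c(50L, 120L),
                               mol_size_range = c(8L, 20L),
                               seed = 0L) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop_value("need 0 <= p_out < p_in <= 1")
  }
  if (n_groups > min(n_compounds, n_sequences)) {
    stop_value("n_groups must be <= min(n_compounds, n_sequences)")
  }
  if (n_groups > length(COMPOUND_MOTIFS)) {
    stop_value("at most %d groups supported", length(COMPOUND_MOTIFS))
  }
  if (min(n_compounds, n_sequences, n_groups) < 1L) {
    stop_value("all counts must be positive")
  }
  stopifnot(length(seq_length_range) == 2L, length(mol_size_range) == 2L,
            seq_length_range[1L] >= 10L, mol_size_range[1L] >= 4L,
            motif_strength >= 0, motif_strength <= 1)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_sequences = as.integer(n_sequences),
                 n_groups = as.integer(n_groups),
                 p_in = p_in, p_out = p_out,
                 motif_strength = motif_strength,
                 seq_length_range = as.integer(seq_length_range),
                 mol_size_range = as.integer(mol_size_range),
                 seed = as.integer(seed)),
            class = "block_model_config")
}

# Balanced group assignment: entities are split as evenly as possible across
# groups, in a seeded random order.
assign_groups <- function(n, G) {
  base <- rep(seq_len(G), length.out = n)
  stats::setNames(base[sample.int(n)], NULL)
}

random_backbone <- function(n_atoms) {
  # linear chain of C with occasional ether O (never two O adjacent, never
  # terminal O at the motif junction)
  atoms <- rep("C", n_atoms)
  if (n_atoms >= 3L) {
    for (i in 2:(n_atoms - 1L)) {
      if (atoms[i - 1L] != "O" && stats::runif(1) < 0.2) atoms[i] <- "O"
    }
  }
  paste(atoms, collapse = "")
}

random_smiles <- function(group, size, motif_strength) {
  has_motif <- stats::runif(1) < motif_strength
  motif <- COMPOUND_MOTIFS[group]
  motif_atoms <- if (has_motif) COMPOUND_MOTIF_ATOMS[group] else 0L
  backbone <- random_backbone(max(3L, size - motif_atoms))
  if (has_motif) paste0(backbone, motif) else backbone
}

random_sequence <- function(group, len, motif_strength) {
  residues <- sample(setdiff(aa_alphabet(), "X"), len, replace = TRUE)
  s <- paste(residues, collapse = "")
  if (stats::runif(1) < motif_strength) {
    motif <- SEQUENCE_MOTIFS[group]
    pos <- sample.int(len - nchar(motif) + 1L, 1L)
    substr(s, pos, pos + nchar(motif) - 1L) <- motif
  }
  s
}

#' Generate a block-structured synthetic interaction dataset
#'
#' @param config a [block_model_config()].
#' @return list with `table` (an [interaction_table()]), `compounds` (named
#'   SMILES vector), `sequences` (named amino-acid string vector),
#'   `compound_groups` and `sequence_groups` (named integer vectors), and the
#'   `config`.
#' @export
generate_block_dataset <- function(config) {
  stopifnot(inherits(config, "block_model_config"))
  with_seed(config$seed, {
    cids <- sprintf("c%03d", seq_len(config$n_compounds))
    sids <- sprintf("s%03d", seq_len(config$n_sequences))
    cg <- stats::setNames(assign_groups(config$n_compounds, config$n_groups), cids)
    sg <- stats::setNames(assign_groups(config$n_sequences, config$n_groups), sids)

    # interaction sampling: one Bernoulli per cell
    P <- matrix(config$p_out, config$n_compounds, config$n_sequences)
    same <- outer(cg, sg, "==")
    P[same] <- config$p_in
    hit <- matrix(stats::runif(length(P)) < P,
                  config$n_compounds, config$n_sequences)
    idx <- which(hit, arr.ind = TRUE)
    positives <- data.frame(compound_id = cids[idx[, 1L]],
                            sequence_id = sids[idx[, 2L]],
                            stringsAsFactors = FALSE)

    sizes <- sample(seq(config$mol_size_range[1L], config$mol_size_range[2L]),
                    config$n_compounds, replace = TRUE)
    compounds <- stats::setNames(vapply(seq_along(cids), function(i) {
      random_smiles(cg[i], sizes[i], config$motif_strength)
    }, ""), cids)

    lens <- sample(seq(config$seq_length_range[1L], config$seq_length_range[2L]),
                   config$n_sequences, replace = TRUE)
    sequences <- stats::setNames(vapply(seq_along(sids), function(i) {
      random_sequence(sg[i], lens[i], config$motif_strength)
    }, ""), sids)

    list(table = interaction_table(positives,
                                   compound_ids = cids, sequence_ids = sids),
         compounds = compounds, sequences = sequences,
         compound_groups = cg, sequence_groups = sg, config = config)
  })
}

#' Ground-truth interaction probability of the block model
#'
#' @param config a [block_model_config()].
#' @param group_c,group_s group indices.
#' @return `p_in` when the groups match, `p_out` otherwise.
#' @export
oracle_interaction_probability <- function(config, group_c, group_s) {
  stopifnot(group_c >= 1, group_c <= config$n_groups,
            group_s >= 1, group_s <= config$n_groups)
  if (group_c == group_s) config$p_in else config$p_out
}

#' Reaction-model configuration
#'
#' @param n_reactions number of reactions.
#' @param reactants_range,products_range,enzymes_range inclusive ranges for
#'   per-reaction set sizes.
#' @param n_rclasses,n_ec_numbers label counts (each `<= n_reactions`).
#' @param seed integer seed.
#' @return a `reaction_model_config` list.
#' @export
reaction_model_config <- function(n_reactions = 40L,
                                  reactants_range = c(1L, 2L),
                                  products_range = c(1L, 2L),
                                  enzymes_range = c(1L, 3L),
                                  n_rclasses = 8L,
                                  n_ec_numbers = 12L,
                                  seed = 0L) {
  stopifnot(n_reactions >= 1L,
            reactants_range[1L] >= 1L, products_range[1L] >= 1L,
            enzymes_range[1L] >= 1L)
  if (n_rclasses > n_reactions || n_ec_numbers > n_reactions) {
    stop_value("class counts must be <= n_reactions")
  }
  structure(list(n_reactions = as.integer(n_reactions),
                 reactants_range = as.integer(reactants_range),
                 products_range = as.integer(products_range),
                 enzymes_range = as.integer(enzymes_range),
                 n_rclasses = as.integer(n_rclasses),
                 n_ec_numbers = as.integer(n_ec_numbers),
                 seed = as.integer(seed)),
            class = "reaction_model_config")
}

#' Generate a synthetic reaction dataset on top of a block dataset
#'
#' Each reaction draws its reactants and products from one compound group and
#' its enzymes from the matching sequence group; RCLASS and EC labels are
#' themselves pinned to groups so that reactions sharing a label share the
#' group. The induced interaction table pairs every reaction compound
#' (reactant or product) with every catalyzing enzyme.
#'
#' @param config a [reaction_model_config()].
#' @param block output of [generate_block_dataset()].
#' @return list with `reactions` (list of [reaction_record()]), `table` (the
#'   induced [interaction_table()]) and `reaction_groups`.
#' @export
generate_reaction_dataset <- function(config, block) {
  stopifnot(inherits(config, "reaction_model_config"))
  G <- block$config$n_groups
  comp_by_group <- split(names(block$compound_groups), block$compound_groups)
  seq_by_group <- split(names(block$sequence_groups), block$sequence_groups)
  with_seed(config$seed, {
    rclass_group <- rep(seq_len(G), length.out = config$n_rclasses)
    ec_group <- rep(seq_len(G), length.out = config$n_ec_numbers)
    reactions <- vector("list", config$n_reactions)
    rgroups <- integer(config$n_reactions)
    for (r in seq_len(config$n_reactions)) {
      rc <- sample.int(config$n_rclasses, 1L)
      g <- rclass_group[rc]
      ecs <- which(ec_group == g)
      ec <- ecs[sample.int(length(ecs), 1L)]
      nr <- sample(seq(config$reactants_range[1L], config$reactants_range[2L]), 1L)
      np <- sample(seq(config$products_range[1L], config$products_range[2L]), 1L)
      ne <- sample(seq(config$enzymes_range[1L], config$enzymes_range[2L]), 1L)
      pool_c <- comp_by_group[[as.character(g)]]
      pool_s <- seq_by_group[[as.character(g)]]
      if (length(pool_c) < nr + np || length(pool_s) < ne) {
        stop_value("group %d too small for reaction of size %d+%d / %d",
                   g, nr, np, ne)
      }
      picks <- sample(pool_c, nr + np)
      reactions[[r]] <- reaction_record(
        sprintf("r%03d", r),
        reactant_ids = picks[seq_len(nr)],
        product_ids = picks[nr + seq_len(np)],
        enzyme_ids = sample(pool_s, ne),
        rclass_id = sprintf("RC%03d", rc),
        ec_number = sprintf("%d.%d.%d.%d", g, 1L, 1L, ec))
      rgroups[r] <- g
    }
    pairs <- do.call(rbind, lapply(reactions, function(rec) {
      expand.grid(compound_id = union(rec$reactant_ids, rec$product_ids),
                  sequence_id = rec$enzyme_ids,
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    }))
    pairs <- pairs[!duplicated(pair_keys(pairs)), , drop = FALSE]
    list(reactions = reactions,
         table = interaction_table(pairs,
                                   compound_ids = names(block$compound_groups),
                                   sequence_ids = names(block$sequence_groups)),
         reaction_groups = rgroups)
  })
}
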