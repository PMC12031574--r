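#' Grammar settings for the synthetic SMILES generator
#'
#' The generator emulates the string-level structure the attribute model
#' consumes: aliphatic chains, branches with balanced parentheses, paired
#' ring-closure digits, aromatic rings, halogens, heteroatoms, double and
#' triple bonds. Strings always tokenize; chemical validity is not required
#' because the method operates on the string itself.
#'
#' @param length_range Backbone length (number of chain positions), sampled
#'   uniformly from this inclusive range.
#' @param p_aromatic Probability that a molecule carries an aromatic ring.
#' @param p_ring Probability of an aliphatic ring on the backbone.
#' @param p_branch Per-position probability of opening a branch.
#' @param p_double Per-position probability of a preceding double bond.
#' @param p_nitrile Per-molecule probability of a terminal nitrile (C#N).
#' @param p_sulfoxide Probability that a sulfur atom is written as S=O.
#' @param atom_probs Named numeric vector of atom symbols and sampling
#'   weights for chain positions.
#' @return List of grammar settings.
#' @export
grammar_config <- function(length_range = c(4L, 12L), p_aromatic = 0.35,
                           p_ring = 0.15, p_branch = 0.25, p_double = 0.12,
                           p_nitrile = 0.3, p_sulfoxide = 0.5,
                           atom_probs = c(C = 0.54, N = 0.10, O = 0.10,
                                          S = 0.11, Cl = 0.08, Br = 0.07)) {
  list(length_range = length_range, p_aromatic = p_aromatic, p_ring = p_ring,
       p_branch = p_branch, p_double = p_double, p_nitrile = p_nitrile,
       p_sulfoxide = p_sulfoxide, atom_probs = atom_probs)
}

sample_atom <- function(cfg) {
  sample(names(cfg$atom_probs), 1L, prob = cfg$atom_probs)
}

# One chain atom, possibly preceded by '=' and possibly written as S=O.
emit_atom <- function(cfg, allow_bond) {
  atom <- sample_atom(cfg)
  out <- character(0)
  if (allow_bond && atom %in% c("C", "N", "O", "S") &&
      stats::runif(1L) < cfg$p_double)
    out <- "="
  out <- c(out, atom)
  if (atom == "S" && stats::runif(1L) < cfg$p_sulfoxide)
    out <- c(out, "=", "O")
  out
}

gen_chain <- function(n, cfg, depth = 0L) {
  tokens <- character(0)
  for (i in seq_len(n)) {
    tokens <- c(tokens, emit_atom(cfg, allow_bond = i > 1L))
    if (depth < 2L && stats::runif(1L) < cfg$p_branch) {
      sub <- gen_chain(sample(1:3, 1L), cfg, depth + 1L)
      tokens <- c(tokens, "(", sub, ")")
    }
  }
  tokens
}

gen_aromatic_ring <- function(cfg) {
  tokens <- c("c", "1")
  for (i in 1:4) {
    tokens <- c(tokens, "c")
    if (stats::runif(1L) < cfg$p_branch) {
      sub <- gen_chain(sample(1:2, 1L), cfg, depth = 1L)
      tokens <- c(tokens, "(", sub, ")")
    }
  }
  c(tokens, "c", "1")
}

gen_aliphatic_ring <- function(cfg) {
  size <- sample(3:5, 1L)
  c("C", "1", rep("C", size), "1")
}

gen_molecule_tokens <- function(cfg) {
  n <- sample(cfg$length_range[1L]:cfg$length_range[2L], 1L)
  tokens <- gen_chain(n, cfg)
  if (stats::runif(1L) < cfg$p_aromatic)
    tokens <- c(tokens, gen_aromatic_ring(cfg))
  else if (stats::runif(1L) < cfg$p_ring)
    tokens <- c(tokens, gen_aliphatic_ring(cfg))
  if (stats::runif(1L) < cfg$p_nitrile) {
    # both orientations occur so the nitrile pair code is observed in more
    # than one triple context
    if (stats::runif(1L) < 0.5) tokens <- c(tokens, "C", "#", "N")
    else tokens <- c("N", "#", "C", tokens)
  }
  tokens
}

#' Generate syntactically valid synthetic SMILES strings
#'
#' Draws `n` strings from the stochastic grammar of [grammar_config()],
#' deterministically per seed. Every string passes the tokenizer round trip;
#' parentheses are balanced and ring-closure digits paired.
#'
#' @param n Number of strings.
#' @param seed Integer seed.
#' @param grammar Settings from [grammar_config()].
#' @return Character vector of length `n`.
#' @export
generate_smiles <- function(n, seed = 1L, grammar = grammar_config()) {
  if (n < 1L) stopf("n must be >= 1")
  with_seed(seed, vapply(seq_len(n), function(i)
    paste0(gen_molecule_tokens(grammar), collapse = ""), character(1L)))
}

#' Define a planted attribute-activity rule
#'
#' A rule ties one attribute (a sequence of 1-3 tokens, counted through its
#' canonical code) to the activity log-odds with a fixed effect size.
#'
#' @param tokens Character vector of 1-3 SMILES-atoms.
#' @param effect Non-zero log-odds contribution per occurrence.
#' @return An object of class `planted_rule` with fields `tokens`, `code`,
#'   `effect` and `label` (`"increase"` or `"decrease"`).
#' @export
planted_rule <- function(tokens, effect) {
  if (effect == 0) stopf("rule effect must be non-zero")
  structure(list(tokens = tokens, code = attribute_code(tokens),
                 effect = effect,
                 label = if (effect > 0) "increase" else "decrease"),
            class = "planted_rule")
}

#' Default planted rules
#'
#' Four rules emulating structural alerts commonly reported for toxicity
#' endpoints: the halogens chlorine and bromine as promoters of increase,
#' triple-bonded (nitrile) nitrogen and double-bonded sulfur as promoters of
#' decrease. Prevalences under the default grammar and the effect sizes are
#' chosen so that each alert carries a comparable, clearly detectable
#' marginal association with activity in the balanced dataset.
#'
#' @return List of [planted_rule()]s.
#' @export
default_rules <- function() {
  list(planted_rule("Cl", 2.0),
       planted_rule("Br", 2.0),
       planted_rule(c("#", "N"), -3.5),
       planted_rule(c("=", "S"), -2.5))
}

#' Assign planted 0/1 activities to SMILES strings
#'
#' Activity is Bernoulli with probability
#' `plogis(intercept + sum(effect * count(code)))`, the intercept being
#' solved so that the marginal active fraction matches `base_rate`.
#' Deterministic per `noise_seed`.
#'
#' @param smiles Character vector of SMILES.
#' @param rules List of [planted_rule()]s.
#' @param base_rate Target marginal active fraction.
#' @param noise_seed Integer seed for the Bernoulli draws.
#' @return Integer vector of 0/1 activities.
#' @export
assign_activity <- function(smiles, rules, base_rate = 0.5, noise_seed = 1L) {
  if (length(rules) == 0L) stopf("at least one rule is required")
  codes <- vapply(rules, function(r) r$code, character(1L))
  effects <- vapply(rules, function(r) r$effect, numeric(1L))
  score <- vapply(smiles, function(s) {
    a <- smiles_attributes(s)
    sum(effects * vapply(codes, function(cd) sum(a == cd), numeric(1L)))
  }, numeric(1L), USE.NAMES = FALSE)
  f <- function(b) mean(stats::plogis(b + score)) - base_rate
  intercept <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  with_seed(noise_seed,
            stats::rbinom(length(smiles), 1L,
                          stats::plogis(intercept + score)))
}

#' Build the default synthetic study scenario
#'
#' Emulates the study conditions of a balanced binary toxicity dataset: a
#' pool of 2616 synthetic compounds with a marginal active rate of 382/2616
#' under the default planted rules, balanced by down-sampling inactives to
#' the number of actives (approximately 382 + 382).
#'
#' @param seed Integer master seed; generation, labelling and balancing use
#'   child seeds derived from it.
#' @param n_pool Pool size before balancing.
#' @param base_rate Marginal active fraction of the pool.
#' @param rules List of [planted_rule()]s (default [default_rules()]).
#' @param grammar Settings from [grammar_config()].
#' @return List with `data` (balanced data frame id/smiles/activity),
#'   `pool` (the full pool) and `rules`.
#' @export
synthetic_scenario <- function(seed = 1L, n_pool = 2616L,
                               base_rate = 382 / 2616,
                               rules = default_rules(),
                               grammar = grammar_config()) {
  smiles <- generate_smiles(n_pool, seed = child_seed(seed, 1L),
                            grammar = grammar)
  activity <- assign_activity(smiles, rules, base_rate = base_rate,
                              noise_seed = child_seed(seed, 2L))
  pool <- data.frame(id = sprintf("M%05d", seq_len(n_pool)),
                     smiles = smiles, activity = activity)
  list(data = balance_dataset(pool, seed = child_seed(seed, 3L)),
       pool = pool, rules = rules)
}

#' Write planted rules as a sidecar TSV
#'
#' @param rules List of [planted_rule()]s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  d <- data.frame(code = vapply(rules, function(r) r$code, character(1L)),
                  tokens = vapply(rules, function(r)
                    paste(r$tokens, collapse = " "), character(1L)),
                  effect = vapply(rules, function(r) r$effect, numeric(1L)),
                  label = vapply(rules, function(r) r$label, character(1L)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
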