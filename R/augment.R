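#' Data augmentation operators for sequence labelling
#'
#' Four operators generate synthetic training variants of a token/label
#' sequence:
#'
#' * **Mention replacement (MR)** — each entity segment (maximal same-label
#'   run with an `"I-"` label) is, with probability `prob`, replaced by
#'   another mention of the same category drawn (with multiplicity) from a
#'   [build_lexicon_index()] inventory. Sequence length may change; the
#'   category and count of entity segments never do. `"O"` segments are
#'   never replaced.
#' * **Synonym replacement (SR)** — each token, independently with
#'   probability `prob`, is replaced by a uniform draw from its synonym set;
#'   tokens with no synonyms are unchanged. Labels and length are preserved.
#' * **Label-wise token replacement (LwTR)** — each token, independently
#'   with probability `prob`, is replaced by a uniform draw (with
#'   multiplicity) from the training-corpus pool of tokens carrying the same
#'   IO label. Labels and length are preserved.
#' * **Shuffle within segments (SiS)** — the sequence is split into maximal
#'   same-label runs (including `"O"` runs by default); with probability
#'   `prob` per run, the tokens inside the run are uniformly permuted.
#'
#' The text these operators produce may be incoherent; that is intentional —
#' the point is to stop the tagger from memorising exact surface forms and
#' push it towards contextual cues.
#'
#' @param seq A [token_label_sequence()].
#' @param index A [build_lexicon_index()] result.
#' @param synlex A [synonym_lexicon()].
#' @param rng A [make_rng()] random source.
#' @param prob Per-segment (MR, SiS) or per-token (SR, LwTR) application
#'   probability.
#' @param entity_only For SiS: shuffle only entity runs, leaving `"O"` runs
#'   fixed.
#' @return A new `token_label_sequence`.
#' @name augmentation_ops
NULL

#' @rdname augmentation_ops
#' @export
mention_replacement <- function(seq, index, rng, prob = 1) {
  stopifnot(inherits(seq, "token_label_sequence"),
            inherits(index, "lexicon_index"))
  runs <- label_runs(seq$labels)
  if (nrow(runs) == 0L) return(seq)
  tokens <- labels <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    idx <- (runs$start[i] + 1L):runs$end[i]
    tokens[[i]] <- seq$tokens[idx]
    labels[[i]] <- seq$labels[idx]
    if (runs$label[i] == "O") next
    if (!rng_bernoulli(rng, 1L, prob)) next
    cat <- sub("^I-", "", runs$label[i])
    inv <- index$mentions[[cat]]
    if (length(inv) == 0L) {
      if (isTRUE(getOption("pathner.verbose")))
        message("mention_replacement: empty inventory for ", cat)
      next
    }
    pick <- inv[[rng_int(rng, 1L, length(inv))]]
    tokens[[i]] <- pick
    labels[[i]] <- rep(runs$label[i], length(pick))
  }
  token_label_sequence(unlist(tokens, use.names = FALSE),
                       unlist(labels, use.names = FALSE))
}

#' @rdname augmentation_ops
#' @export
synonym_replacement <- function(seq, synlex, rng, prob = 1) {
  stopifnot(inherits(seq, "token_label_sequence"),
            inherits(synlex, "synonym_lexicon"))
  tokens <- seq$tokens
  for (i in seq_along(tokens)) {
    if (!rng_bernoulli(rng, 1L, prob)) next
    syn <- synonyms_of(synlex, tokens[i])
    if (length(syn) == 0L) next
    tokens[i] <- syn[rng_int(rng, 1L, length(syn))]
  }
  token_label_sequence(tokens, seq$labels)
}

#' @rdname augmentation_ops
#' @export
label_wise_token_replacement <- function(seq, index, rng, prob = 1) {
  stopifnot(inherits(seq, "token_label_sequence"),
            inherits(index, "lexicon_index"))
  tokens <- seq$tokens
  for (i in seq_along(tokens)) {
    if (!rng_bernoulli(rng, 1L, prob)) next
    pool <- index$token_pools[[seq$labels[i]]]
    if (length(pool) == 0L) {
      if (isTRUE(getOption("pathner.verbose")))
        message("label_wise_token_replacement: empty pool for ", seq$labels[i])
      next
    }
    tokens[i] <- pool[rng_int(rng, 1L, length(pool))]
  }
  token_label_sequence(tokens, seq$labels)
}

#' @rdname augmentation_ops
#' @export
shuffle_within_segments <- function(seq, rng, prob = 1, entity_only = FALSE) {
  stopifnot(inherits(seq, "token_label_sequence"))
  tokens <- seq$tokens
  runs <- label_runs(seq$labels)
  for (i in seq_len(nrow(runs))) {
    if (entity_only && runs$label[i] == "O") next
    n <- runs$end[i] - runs$start[i]
    if (!rng_bernoulli(rng, 1L, prob)) next
    if (n < 2L) next
    idx <- (runs$start[i] + 1L):runs$end[i]
    tokens[idx] <- rng_permute(rng, tokens[idx])
  }
  token_label_sequence(tokens, seq$labels)
}

# ---- policy ----------------------------------------------------------------

.policy_order <- c("MR", "SR", "LwTR", "SiS")

#' Bernoulli-gated augmentation policy
#'
#' A policy is an ordered list of operator steps, each with an instance-level
#' gate probability `p`: for every training instance, a Bernoulli(`p`) draw
#' decides whether that operator is applied at all. Once gated on, MR and SiS
#' act per segment and SR and LwTR per token with an internal rate `inner`
#' defaulting to the same `p`. When all four operators are enabled their
#' order is fixed to MR, SR, LwTR, SiS; subsets keep that relative order.
#'
#' @param p Gate probability (scalar recycled, or one per step). The default
#'   0.1 with all four operators is the configuration selected on the
#'   original corpus.
#' @param steps Operator names, a subset of `c("MR","SR","LwTR","SiS")` in
#'   canonical order.
#' @param inner Within-instance rate per step (defaults to `p`).
#' @param entity_only_sis Restrict SiS to entity runs.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(p = 0.1, steps = .policy_order, inner = p,
                                entity_only_sis = FALSE) {
  steps <- as.character(steps)
  bad <- setdiff(steps, .policy_order)
  if (length(bad) > 0L)
    stop("unknown augmentation operator: ", paste(bad, collapse = ", "))
  if (anyDuplicated(steps)) stop("duplicate operator in policy")
  if (!identical(steps, intersect(.policy_order, steps)))
    stop("operators must appear in the fixed order MR, SR, LwTR, SiS")
  p <- rep_len(p, length(steps)); inner <- rep_len(inner, length(steps))
  if (any(p < 0 | p > 1 | inner < 0 | inner > 1))
    stop("probabilities must lie in [0, 1]")
  structure(list(steps = steps, p = p, inner = inner,
                 entity_only_sis = isTRUE(entity_only_sis)),
            class = "augmentation_policy")
}

#' @export
print.augmentation_policy <- function(x, ...) {
  cat("<augmentation_policy>\n")
  for (i in seq_along(x$steps))
    cat(sprintf("  %-5s gate p = %.3f, inner rate = %.3f\n",
                x$steps[i], x$p[i], x$inner[i]))
  invisible(x)
}

#' Apply an augmentation policy to one instance
#'
#' Operators are composed left to right in the policy's order; each is
#' applied only if its instance-level Bernoulli gate fires. The result
#' carries an `"applied"` attribute naming the steps whose gates fired.
#'
#' @param seq A [token_label_sequence()].
#' @param policy An [augmentation_policy()].
#' @param index Lexicon index (required when MR or LwTR is in the policy).
#' @param synlex Synonym lexicon (required when SR is in the policy).
#' @param rng A [make_rng()] random source.
#' @return An augmented `token_label_sequence`.
#' @export
apply_policy <- function(seq, policy, index = NULL, synlex = NULL, rng) {
  stopifnot(inherits(policy, "augmentation_policy"))
  if (any(policy$steps %in% c("MR", "LwTR")) && is.null(index))
    stop("policy includes MR/LwTR but no lexicon index was given")
  if ("SR" %in% policy$steps && is.null(synlex))
    stop("policy includes SR but no synonym lexicon was given")
  applied <- character()
  for (i in seq_along(policy$steps)) {
    if (!rng_bernoulli(rng, 1L, policy$p[i])) next
    applied <- c(applied, policy$steps[i])
    seq <- switch(policy$steps[i],
      MR = mention_replacement(seq, index, rng, prob = policy$inner[i]),
      SR = synonym_replacement(seq, synlex, rng, prob = policy$inner[i]),
      LwTR = label_wise_token_replacement(seq, index, rng,
                                          prob = policy$inner[i]),
      SiS = shuffle_within_segments(seq, rng, prob = policy$inner[i],
                                    entity_only = policy$entity_only_sis))
  }
  attr(seq, "applied") <- applied
  seq
}

#' Augment a corpus of token/label sequences
#'
#' Applies the policy independently to each sequence in corpus order, so a
#' fixed seed reproduces the augmented corpus bit for bit. The lexicon index
#' is read-only: augmented output never feeds back into it.
#'
#' @inheritParams apply_policy
#' @param seqs List of [token_label_sequence()] objects.
#' @return A list of augmented sequences with an `"op_counts"` attribute
#'   (applications per operator).
#' @export
augment_corpus <- function(seqs, policy, index = NULL, synlex = NULL, rng) {
  counts <- stats::setNames(integer(length(policy$steps)), policy$steps)
  out <- lapply(seqs, function(s) {
    a <- apply_policy(s, policy, index, synlex, rng)
    for (st in attr(a, "applied")) counts[st] <<- counts[st] + 1L
    attr(a, "applied") <- NULL
    a
  })
  attr(out, "op_counts") <- counts
  out
}
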