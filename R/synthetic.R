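# Seeded generator of annotated synthetic breast-pathology reports.
#
# Reports are templated prose assembled from data-file lexicons and emitted
# born-annotated: every entity chunk's word range is recorded at generation
# time, so ground truth is exact by construction. Two dialects emulate an
# internal/external distribution shift: the external dialect prefers
# abbreviations and short forms ("uoq" for "upper outer quadrant",
# "10/2 cm" for "10 o'clock 2 cm"), different report skeletons, and more
# frequent negation. Mentions inside negation constructs ("no evidence of
# <subtype>") are labelled "O" — negated findings are not entities — which
# makes negation a learnable context signal. The language is deliberately
# simplistic; benchmarks built on it support relative comparisons
# (augmented vs not, internal vs shifted), not absolute realism claims.

#' Load the report generation grammar
#'
#' Lexicons and templates live in plain-text data files so the grammar can
#' be extended without touching the generator: subtype phrases (with
#' cancer-positive flags and abbreviations), grade phrases, position
#' phrases (internal and external surface forms), finding-line templates,
#' negation templates, filler lines and per-dialect report headers.
#'
#' @param dir Directory holding the grammar files; defaults to the bundled
#'   grammar.
#' @return An object of class `generation_grammar`.
#' @export
report_grammar <- function(dir = system.file("extdata", "grammar",
                                             package = "pathner")) {
  rl <- function(f) {
    x <- readLines(file.path(dir, f), warn = FALSE, encoding = "UTF-8")
    x[nzchar(x) & !startsWith(x, "#")]
  }
  sub_f <- strsplit(rl("subtypes.tsv"), "\t", fixed = TRUE)
  subtypes <- data.frame(
    phrase = vapply(sub_f, `[`, character(1), 1L),
    positive = vapply(sub_f, `[`, character(1), 2L) == "1",
    abbrev = vapply(sub_f, function(x) if (length(x) >= 3L) x[3L] else NA_character_,
                    character(1)),
    stringsAsFactors = FALSE)
  pos_f <- strsplit(rl("positions.tsv"), "\t", fixed = TRUE)
  positions <- data.frame(
    internal = vapply(pos_f, `[`, character(1), 1L),
    external = vapply(pos_f, `[`, character(1), 2L),
    stringsAsFactors = FALSE)
  tpl_f <- strsplit(rl("templates.txt"), "\t", fixed = TRUE)
  templates <- data.frame(sig = vapply(tpl_f, `[`, character(1), 1L),
                          template = vapply(tpl_f, `[`, character(1), 2L),
                          stringsAsFactors = FALSE)
  g <- structure(list(subtypes = subtypes, grades = rl("grades.txt"),
                      positions = positions, templates = templates,
                      negation = rl("negation.txt"), filler = rl("filler.txt"),
                      headers = list(internal = rl("headers_internal.txt"),
                                     external = rl("headers_external.txt"))),
                 class = "generation_grammar")
  for (nm in c("grades", "negation", "filler"))
    if (length(g[[nm]]) == 0L) stop("empty grammar lexicon: ", nm)
  if (nrow(subtypes) == 0L || nrow(positions) == 0L ||
      nrow(templates) == 0L)
    stop("empty grammar lexicon")
  g
}

#' Configuration of the synthetic corpus generator
#'
#' Rates are chosen to mirror the per-report entity frequencies of the
#' corpus the generator emulates (about 1.08 subtype, 0.71 grade and 0.74
#' position entities per report). `subtype_rate` is the expected number of
#' subtype mentions per report (negated mentions included);
#' `grade_rate`/`position_rate` are expected mentions per report and must
#' not exceed `subtype_rate`, since grades and positions attach to
#' findings.
#'
#' @param n_reports Number of reports to generate.
#' @param dialect `"internal"` or `"external"` surface conventions.
#' @param subtype_rate,grade_rate,position_rate Expected mentions per
#'   report. Each non-negated finding carries a grade with probability
#'   `grade_rate / subtype_rate` (cancer findings only — benign lesions are
#'   not graded) and a position with probability
#'   `position_rate / subtype_rate`.
#' @param negation_rate Probability that a subtype mention sits inside a
#'   negation template (and is therefore labelled `"O"`).
#' @param misspelling_rate Per-word probability of a 1-edit character
#'   corruption.
#' @param abbreviation_rate Probability of dialect short forms (e.g. "uoq",
#'   "dcis", "10/2 cm").
#' @param collision_rate Probability that a finding embeds a grade phrase
#'   inside the subtype span ("invasive poorly differentiated carcinoma,
#'   high nuclear grade"), labelled per the outer span.
#' @param clock_rate Probability a position mention uses clock-face
#'   notation.
#' @param cancer_prevalence Fraction of reports with at least one
#'   non-negated cancer-positive finding.
#' @param seed Generator seed.
#' @return An object of class `corpus_config`.
#' @export
corpus_config <- function(n_reports, dialect = c("internal", "external"),
                          subtype_rate = 1.08, grade_rate = 0.71,
                          position_rate = 0.74, negation_rate = 0.12,
                          misspelling_rate = 0.02, abbreviation_rate = 0.05,
                          collision_rate = 0.05, clock_rate = 0.3,
                          cancer_prevalence = 0.6, seed = 1L) {
  dialect <- match.arg(dialect)
  rates <- c(negation_rate, misspelling_rate, abbreviation_rate,
             collision_rate, clock_rate, cancer_prevalence)
  stopifnot(n_reports >= 1L, all(rates >= 0 & rates <= 1),
            subtype_rate >= 1, grade_rate <= subtype_rate,
            position_rate <= subtype_rate)
  structure(list(n_reports = as.integer(n_reports), dialect = dialect,
                 subtype_rate = subtype_rate, grade_rate = grade_rate,
                 position_rate = position_rate,
                 negation_rate = negation_rate,
                 misspelling_rate = misspelling_rate,
                 abbreviation_rate = abbreviation_rate,
                 collision_rate = collision_rate, clock_rate = clock_rate,
                 cancer_prevalence = cancer_prevalence,
                 seed = as.integer(seed)),
            class = "corpus_config")
}

#' Corrupt a word by one character edit
#'
#' Applies one random substitution, deletion or adjacent transposition,
#' emulating the typographic errors found in real reports ("caricinoma",
#' "fetures"). The result differs from the input and lies in its 1-edit
#' (Damerau) neighborhood. Words shorter than two characters are returned
#' unchanged.
#'
#' @param word A lowercase word.
#' @param rng A [make_rng()] random source.
#' @return The corrupted word.
#' @export
corrupt_word <- function(word, rng) {
  n <- nchar(word)
  if (n < 2L) return(word)
  op <- rng_int(rng, 1L, 3L)
  ch <- strsplit(word, "")[[1]]
  if (op == 3L) {
    cand <- which(ch[-n] != ch[-1L])
    if (length(cand) == 0L) op <- 1L else {
      i <- cand[rng_int(rng, 1L, length(cand))]
      ch[c(i, i + 1L)] <- ch[c(i + 1L, i)]
      return(paste(ch, collapse = ""))
    }
  }
  if (op == 2L) {
    i <- rng_int(rng, 1L, n)
    return(paste(ch[-i], collapse = ""))
  }
  i <- rng_int(rng, 1L, n)
  pool <- setdiff(letters, ch[i])
  ch[i] <- pool[rng_int(rng, 1L, length(pool))]
  paste(ch, collapse = "")
}

# tokens joined into display text: no space before closing punctuation and
# apostrophes/slashes, none after opening ones
.detokenize_offsets <- function(tokens) {
  no_space_before <- c(",", ".", ";", ":", ")", "'", "/", "?")
  no_space_after <- c("(", "'", "/")
  text <- ""
  start <- integer(length(tokens))
  prev <- ""
  for (i in seq_along(tokens)) {
    sep <- if (i == 1L) "" else if (tokens[i] %in% no_space_before ||
                                    prev %in% no_space_after) "" else " "
    text <- paste0(text, sep, tokens[i])
    start[i] <- nchar(text) - nchar(tokens[i])
    prev <- tokens[i]
  }
  list(text = text, start = start, end = start + nchar(tokens))
}

# fill one template: literal pieces are "O", each {slot} is a chunk of given
# category ("O" for negated or non-entity slots)
.fill_template <- function(tpl, fills) {
  out <- list(tokens = character(), category = character())
  push <- function(s, cat) {
    tk <- tokenize_words(s)$token
    if (length(tk) == 0L) return()
    out$tokens <<- c(out$tokens, tk)
    out$category <<- c(out$category, rep(cat, length(tk)))
  }
  rest <- tpl
  repeat {
    m <- regexpr("\\{[a-z]+\\}", rest)
    if (m == -1L) { push(rest, "O"); break }
    if (m > 1L) push(substr(rest, 1L, m - 1L), "O")
    slot <- substr(rest, m + 1L, m + attr(m, "match.length") - 2L)
    f <- fills[[slot]]
    if (is.null(f)) stop("template slot with no fill: ", slot)
    push(f$surface, f$category)
    rest <- substr(rest, m + attr(m, "match.length"), nchar(rest))
  }
  out
}

.pick <- function(rng, x) x[[rng_int(rng, 1L, length(x))]]

.position_surface <- function(grammar, config, rng) {
  external_form <- rng_bernoulli(rng, 1L, config$abbreviation_rate)
  if (rng_bernoulli(rng, 1L, config$clock_rate)) {
    h <- rng_int(rng, 1L, 12L); d <- rng_int(rng, 1L, 12L)
    if (config$dialect == "external" && external_form)
      sprintf("%d / %d cm from the nipple", h, d)
    else
      sprintf("%d o'clock %d cm from the nipple", h, d)
  } else {
    i <- rng_int(rng, 1L, nrow(grammar$positions))
    if (config$dialect == "external" && external_form)
      grammar$positions$external[i]
    else grammar$positions$internal[i]
  }
}

.subtype_surface <- function(row, config, rng) {
  if (!is.na(row$abbrev) &&
      rng_bernoulli(rng, 1L, config$abbreviation_rate))
    row$abbrev
  else row$phrase
}

.generate_report <- function(report_id, config, grammar, rng) {
  q <- config$negation_rate
  p_g <- min(1, config$grade_rate / config$subtype_rate)
  p_p <- min(1, config$position_rate / config$subtype_rate)
  cancer <- rng_bernoulli(rng, 1L, config$cancer_prevalence)
  n_findings <- 1L + rng_pois(rng, 1L, config$subtype_rate - 1)

  pos_rows <- which(grammar$subtypes$positive)
  neg_rows <- which(!grammar$subtypes$positive)

  lines <- list()
  headers <- grammar$headers[[config$dialect]]
  lines[[1]] <- .fill_template(.pick(rng, headers), list())

  emitted_positive <- FALSE
  for (k in seq_len(n_findings)) {
    if (k == 1L) {
      if (cancer) {
        row_i <- pos_rows[rng_int(rng, 1L, length(pos_rows))]
        negated <- FALSE
      } else {
        row_i <- neg_rows[rng_int(rng, 1L, length(neg_rows))]
        negated <- rng_bernoulli(rng, 1L, q)
      }
    } else if (cancer) {
      row_i <- rng_int(rng, 1L, nrow(grammar$subtypes))
      negated <- rng_bernoulli(rng, 1L, q)
    } else if (rng_bernoulli(rng, 1L, q)) {
      # a negated mention of a cancer-positive finding: the trap case
      row_i <- pos_rows[rng_int(rng, 1L, length(pos_rows))]
      negated <- TRUE
    } else {
      row_i <- neg_rows[rng_int(rng, 1L, length(neg_rows))]
      negated <- rng_bernoulli(rng, 1L, q)
    }
    row <- grammar$subtypes[row_i, ]
    surface <- .subtype_surface(row, config, rng)

    if (negated) {
      tpl <- .pick(rng, grammar$negation)
      lines[[length(lines) + 1L]] <- .fill_template(
        tpl, list(subtype = list(surface = surface, category = "O")))
      next
    }
    if (!row$positive) {
      # benign findings never carry a cancer grade
      has_g <- FALSE
    } else has_g <- rng_bernoulli(rng, 1L, p_g)
    has_p <- rng_bernoulli(rng, 1L, p_p)
    if (row$positive) emitted_positive <- TRUE

    if (has_g && identical(surface, row$phrase) &&
        rng_bernoulli(rng, 1L, config$collision_rate) &&
        startsWith(surface, "invasive ")) {
      # grade phrase embedded inside the subtype span, labelled per the
      # outer span ("invasive poorly differentiated carcinoma, ...")
      adj <- .pick(rng, c("poorly differentiated", "moderately differentiated",
                          "well differentiated"))
      surface <- sub("^invasive ", paste0("invasive ", adj, " "), surface)
    }
    sig <- paste0("S", if (has_g) "G" else "", if (has_p) "P" else "")
    tpls <- grammar$templates$template[grammar$templates$sig == sig]
    fills <- list(subtype = list(surface = surface,
                                 category = "cancer_subtype"))
    if (has_g)
      fills$grade <- list(surface = .pick(rng, grammar$grades),
                          category = "cancer_grade")
    if (has_p)
      fills$position <- list(surface = .position_surface(grammar, config, rng),
                             category = "lesion_position")
    lines[[length(lines) + 1L]] <- .fill_template(.pick(rng, tpls), fills)
  }

  n_filler <- 1L + rng_int(rng, 1L, 3L)
  for (i in seq_len(n_filler)) {
    tpl <- .pick(rng, grammar$filler)
    lines[[length(lines) + 1L]] <- .fill_template(
      tpl, list(num = list(surface = as.character(rng_int(rng, 1L, 9L)),
                           category = "O")))
  }

  tokens <- unlist(lapply(lines, `[[`, "tokens"), use.names = FALSE)
  category <- unlist(lapply(lines, `[[`, "category"), use.names = FALSE)

  if (config$misspelling_rate > 0) {
    for (i in seq_along(tokens)) {
      if (grepl("^[a-z]{2,}$", tokens[i]) &&
          rng_bernoulli(rng, 1L, config$misspelling_rate))
        tokens[i] <- corrupt_word(tokens[i], rng)
    }
  }

  runs <- label_runs(category)
  ent <- runs[runs$label != "O", , drop = FALSE]
  spans <- entity_spans(ent$start, ent$end, ent$label)

  dt <- .detokenize_offsets(tokens)
  tok_df <- data.frame(token = tokens, start = dt$start, end = dt$end,
                       stringsAsFactors = FALSE)
  annotated_report(report_id, dt$text, spans = spans,
                   report_label = emitted_positive, tokens = tok_df)
}

#' Generate a corpus of annotated synthetic pathology reports
#'
#' Every emitted report is validated against the annotation invariants at
#' emission, carries exact ground-truth spans, and has
#' `report_label = TRUE` iff a non-negated cancer-positive subtype was
#' emitted. The same (config, grammar) pair reproduces the corpus bit for
#' bit.
#'
#' @param config A [corpus_config()].
#' @param grammar A [report_grammar()].
#' @return List of `annotated_report`s with a `"config"` attribute.
#' @export
generate_corpus <- function(config, grammar = report_grammar()) {
  stopifnot(inherits(config, "corpus_config"),
            inherits(grammar, "generation_grammar"))
  rng <- make_rng(config$seed)
  out <- lapply(seq_len(config$n_reports), function(i) {
    .generate_report(sprintf("%s-%05d", config$dialect, i), config, grammar,
                     rng)
  })
  attr(out, "config") <- config
  out
}

#' Build the internal/external distribution-shift benchmark
#'
#' Generates four disjoint corpora: training, validation and internal test
#' sets in the internal dialect, plus an external test set in the external
#' dialect with elevated abbreviation and negation rates. The default split
#' sizes (968 / 276 / 194 / 55) mirror the report counts of the corpora the
#' generator emulates. Report ids are prefixed by split, so splits are
#' id-disjoint by construction.
#'
#' @param n Named integer vector of split sizes.
#' @param seed Benchmark seed; per-split generator seeds are derived from
#'   it.
#' @param internal,external Optional lists of [corpus_config()] overrides
#'   for the two dialects.
#' @param grammar A [report_grammar()].
#' @return Named list of corpora: `train`, `val`, `test_internal`,
#'   `test_external`.
#' @export
make_shift_benchmark <- function(n = c(train = 968L, val = 276L,
                                       test_internal = 194L,
                                       test_external = 55L),
                                 seed = 1L, internal = list(),
                                 external = list(),
                                 grammar = report_grammar()) {
  stopifnot(all(c("train", "val", "test_internal", "test_external") %in%
                  names(n)))
  rng <- make_rng(seed)
  seeds <- vapply(1:4, function(i) rng_child_seed(rng), integer(1))
  ext_defaults <- list(negation_rate = 0.25, misspelling_rate = 0.05,
                       abbreviation_rate = 0.55)
  mk <- function(size, dialect, sd, overrides) {
    args <- c(list(n_reports = size, dialect = dialect, seed = sd), overrides)
    do.call(corpus_config, args)
  }
  cfgs <- list(
    train = mk(n[["train"]], "internal", seeds[1], internal),
    val = mk(n[["val"]], "internal", seeds[2], internal),
    test_internal = mk(n[["test_internal"]], "internal", seeds[3], internal),
    test_external = mk(n[["test_external"]], "external", seeds[4],
                       utils::modifyList(ext_defaults, external)))
  out <- lapply(names(cfgs), function(nm) {
    corpus <- generate_corpus(cfgs[[nm]], grammar)
    for (i in seq_along(corpus))
      corpus[[i]]$report_id <- paste0(nm, "-", corpus[[i]]$report_id)
    corpus
  })
  names(out) <- names(cfgs)
  attr(out, "configs") <- cfgs
  out
}
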