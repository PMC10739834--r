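# word pools of the generator: a shared function-word/pseudo-word base,
# a lexicon sprinkle giving every category sampling variance, content words
# with known concreteness norms, and per-category entity gazetteers split
# into a base-noise half and a carrier-reserve half (so planted unique
# entities never collide with background mentions)
synthetic_pools <- function() {
  fw <- c("the", "a", "of", "to", "in", "and", "on", "at", "for", "with",
          "was", "is", "that", "it", "but")
  pseudo <- c("borlit", "dantor", "meskin", "tralvo", "quendel", "sarnip",
              "veldro", "jintal", "porvek", "lasmun", "tirgov", "nembla",
              "cursov", "haldrin", "opresta", "wintal", "zorbel", "fimrak",
              "prindle", "askovel", "mitran", "belfor", "dovkin", "surmel",
              "crenta", "volpin", "terbak", "unswil", "grolet", "torvin")
  sprinkle <- c("i", "we", "she", "they", "you", "very", "never", "good",
                "bad", "think", "remember", "yesterday", "today", "tomorrow",
                "aware", "bright", "loud", "warm", "near", "morning",
                "happy", "sad", "went")
  words <- c(fw, pseudo, sprinkle)
  weights <- c(rep(2, length(fw)), rep(3, length(pseudo)),
               rep(0.35, length(sprinkle)))
  list(
    words = words, weights = weights / sum(weights),
    content_high = c("apple", "car", "table", "water", "house", "tree",
                     "chair", "bread", "book", "window"),
    content_low = c("freedom", "justice", "belief", "theory", "logic",
                    "doubt", "purpose", "concept"),
    entities = list(
      People = list(base = c("Mary", "Paul", "Adam", "John", "Sarah"),
                    reserve = c("Lucy", "Peter", "Maria", "Carlos", "Yuki",
                                "Omar", "Ingrid", "Pablo", "Chen", "Fatima")),
      Temporal_details = list(base = c("monday", "friday", "january", "july"),
                              reserve = c("christmas", "easter", "midnight",
                                          "noon", "october", "december")),
      Spatial_details = list(base = c("tokyo", "london", "paris", "rome"),
                             reserve = c("berlin", "madrid", "chicago",
                                         "boston", "seattle", "denver",
                                         "kyoto", "lisbon", "oslo", "cairo")),
      Quantity_details = list(base = c("ten", "three", "first"),
                              reserve = c("20%", "42", "second", "dozen",
                                          "15%", "fifty", "seven", "twelve"))
    )
  )
}

# carrier words per plantable lexicon feature; each word hits the planted
# feature's categories and nothing that feeds the concreteness score
lexicon_carriers <- function() {
  list(
    tone_pos = c("good", "nice"), tone_neg = c("bad", "awful"),
    Cognition = c("think", "believe"), memory = c("remember", "recall"),
    focuspast = c("yesterday", "earlier"),
    focuspresent = c("today", "currently"),
    focusfuture = c("tomorrow", "soon"),
    Self_reference = c("i", "we"), Other_reference = c("they", "she"),
    Perceptual_details = c("bright", "loud", "warm", "aware"),
    Contextual_Embedding = c("near", "around", "morning"),
    Reality_Monitoring = c("excited", "proud")
  )
}

# feature -> signed category sets, for analytic baseline percentages
feature_category_map <- function() {
  list(
    tone_pos = c(tone_pos = 1), tone_neg = c(tone_neg = 1),
    Cognition = c(Cognition = 1), memory = c(memory = 1),
    focuspast = c(focuspast = 1), focuspresent = c(focuspresent = 1),
    focusfuture = c(focusfuture = 1),
    Self_reference = c(i = 1, we = 1),
    Other_reference = c(shehe = 1, they = 1, you = 1),
    Perceptual_details = c(attention = 1, visual = 1, auditory = 1, feeling = 1),
    Contextual_Embedding = c(space = 1, motion = 1, time = 1),
    Reality_Monitoring = c(attention = 1, visual = 1, auditory = 1,
                           feeling = 1, space = 1, motion = 1, time = 1,
                           Affect = 1, Cognition = -1)
  )
}

#' Declare a planted class effect
#'
#' @param feature One of the 26 style features.
#' @param delta Truthful-minus-deceptive target shift: percentage points
#'   for lexicon carriers, words for the length carrier, unique entities
#'   for entity carriers, score units for the concreteness carrier.
#' @param carrier `"lexicon"`, `"length"`, `"entity"` or `"concreteness"`;
#'   `NULL` picks the natural carrier of the feature.
#' @return One-row tibble for `planted_effects`.
#' @export
planted_effect <- function(feature, delta, carrier = NULL) {
  if (is.null(carrier)) {
    carrier <- if (feature %in% names(lexicon_carriers())) "lexicon"
    else if (feature %in% c("num_words", "num_sentences", "num_syllables")) "length"
    else if (feature %in% c("People", "Temporal_details", "Spatial_details",
                            "Quantity_details")) "entity"
    else if (feature == "Concreteness_score") "concreteness"
    else stop("no carrier available to plant feature `", feature, "`",
              call. = FALSE)
  }
  tibble::tibble(feature = feature, delta = delta, carrier = carrier)
}

#' Configuration of the synthetic two-class corpus generator
#'
#' Emulates the structure of short-statement deception corpora from three
#' nominal domains: the opinion-like domain has five statements per
#' subject, roughly half truthful and half deceptive (the extra statement
#' alternates between classes across subjects), the other domains one
#' statement per subject, balanced classes. Texts are template-assembled
#' word sequences from fixed published pools, with optional planted class
#' effects whose expected truthful-minus-deceptive shifts are recorded in
#' the returned ground truth.
#'
#' @param domains Subset of `c("opinion", "memory", "intention")`.
#' @param n_subjects Subjects per domain (scalar or named vector).
#' @param length_mean,length_sd Word-length distribution (min length 6).
#' @param planted_effects Tibble of [planted_effect()] rows (empty = null
#'   corpus).
#' @param domain_specific If `TRUE`, class-marker tokens (and so the
#'   classifier-visible signal) differ per domain and are absent from the
#'   other domains' vocabularies.
#' @param marker_rate Probability a statement carries its class marker
#'   token (0 disables the classifier signal).
#' @param entity_noise Probability a statement carries one background
#'   entity mention (class-independent).
#' @param n_content_words Content (concreteness-bearing) words per text.
#' @param seed Generator seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(domains = c("opinion", "memory", "intention"),
                             n_subjects = c(opinion = 50, memory = 150,
                                            intention = 150),
                             length_mean = 50, length_sd = 12,
                             planted_effects = NULL,
                             domain_specific = FALSE,
                             marker_rate = 0, entity_noise = 0.5,
                             n_content_words = 3, seed = 1L) {
  domains <- match.arg(domains, several.ok = TRUE)
  if (length(n_subjects) == 1L && is.null(names(n_subjects))) {
    n_subjects <- stats::setNames(rep(n_subjects, length(domains)), domains)
  }
  stopifnot(all(domains %in% names(n_subjects)), all(n_subjects[domains] >= 1),
            length_mean >= 6)
  if (is.null(planted_effects)) {
    planted_effects <- tibble::tibble(feature = character(),
                                      delta = numeric(), carrier = character())
  }
  bad <- setdiff(planted_effects$feature, style_features())
  if (length(bad)) {
    stop("unknown planted feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ok_carrier <- planted_effects$carrier %in%
    c("lexicon", "length", "entity", "concreteness")
  if (!all(ok_carrier)) stop("unknown carrier", call. = FALSE)
  no_carrier <- planted_effects$feature[
    (planted_effects$carrier == "lexicon" &
       !planted_effects$feature %in% names(lexicon_carriers())) |
    (planted_effects$carrier == "entity" &
       !planted_effects$feature %in% c("People", "Temporal_details",
                                       "Spatial_details", "Quantity_details"))]
  if (length(no_carrier)) {
    stop("no carrier available to plant feature(s): ",
         paste(no_carrier, collapse = ", "), call. = FALSE)
  }
  structure(list(domains = domains, n_subjects = n_subjects,
                 length_mean = length_mean, length_sd = length_sd,
                 planted_effects = planted_effects,
                 domain_specific = domain_specific,
                 marker_rate = marker_rate, entity_noise = entity_noise,
                 n_content_words = as.integer(n_content_words),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# analytic baseline value of a lexicon-backed feature under the base pool
baseline_feature_pct <- function(feature, pools, lexicon) {
  lex <- compile_lexicon(lexicon)
  signs <- feature_category_map()[[feature]]
  val <- 0
  for (cat in names(signs)) {
    entries <- lex[[cat]]
    hit <- pools$words %in% entries$exact
    for (stem in entries$stems) hit <- hit | startsWith(pools$words, stem)
    val <- val + signs[[cat]] * 100 * sum(pools$weights[hit])
  }
  unname(val)
}

#' Generate a labelled synthetic corpus with recorded ground truth
#'
#' @param config A [synthetic_config()].
#' @param lexicon Lexicon used to compute the analytic expected shifts
#'   (default: the fixture lexicon the package extracts with).
#' @return List `corpus` (a `veristyle_corpus`) and `truth` (tibble
#'   `feature, planted, carrier, expected_shift` for all 26 features, with
#'   the pools, carrier words and marker tokens in its attributes).
#' @export
generate_corpus <- function(config, lexicon = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(lexicon)) {
    lexicon <- read_dic(system.file("extdata", "fixture_lexicon.dic",
                                    package = "veristyle", mustWork = TRUE))
  }
  pools <- synthetic_pools()
  carriers <- lexicon_carriers()
  pe <- config$planted_effects
  high_mean <- mean_concreteness_pool(pools$content_high)
  low_mean <- mean_concreteness_pool(pools$content_low)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)

  plan <- dplyr::bind_rows(lapply(config$domains, function(dom) {
    ns <- config$n_subjects[[dom]]
    if (dom == "opinion") {
      dplyr::bind_rows(lapply(seq_len(ns), function(s) {
        labs <- c(rep("truthful", 2), rep("deceptive", 2),
                  if (s %% 2 == 1) "truthful" else "deceptive")
        tibble::tibble(domain = dom,
                       subject_id = sprintf("%s_s%03d", dom, s),
                       veracity = labs)
      }))
    } else {
      tibble::tibble(domain = dom,
                     subject_id = sprintf("%s_s%03d", dom, seq_len(ns)),
                     veracity = rep(c("truthful", "deceptive"), length.out = ns))
    }
  }))
  plan$id <- sprintf("%s_%05d", plan$domain, seq_len(nrow(plan)))

  len_delta <- sum(pe$delta[pe$carrier == "length"])
  lex_plants <- pe[pe$carrier == "lexicon", ]
  ent_plants <- pe[pe$carrier == "entity", ]
  con_plant <- pe[pe$carrier == "concreteness", ]
  mix_q <- if (nrow(con_plant) == 1L) {
    q <- con_plant$delta / (high_mean - low_mean)
    if (q < 0 || q > 1) stop("concreteness delta out of range", call. = FALSE)
    q
  } else NA_real_

  texts <- vapply(seq_len(nrow(plan)), function(i) {
    truthful <- plan$veracity[i] == "truthful"
    dom <- plan$domain[i]
    mu <- config$length_mean + if (truthful) len_delta else 0
    L <- max(6L, as.integer(round(stats::rnorm(1, mu, config$length_sd))))
    toks <- sample(pools$words, L, replace = TRUE, prob = pools$weights)
    if (truthful && nrow(lex_plants) > 0L) {
      for (j in seq_len(nrow(lex_plants))) {
        hit <- stats::runif(L) < lex_plants$delta[j] / 100
        if (any(hit)) {
          toks[hit] <- sample(carriers[[lex_plants$feature[j]]], sum(hit),
                              replace = TRUE)
        }
      }
    }
    # content words with known concreteness norms
    nc <- min(config$n_content_words, L)
    if (nc > 0L) {
      slots <- sample.int(L, nc)
      toks[slots] <- if (nrow(con_plant) == 1L) {
        if (truthful) sample(pools$content_high, nc, replace = TRUE)
        else {
          low <- stats::runif(nc) < mix_q
          ifelse(low, sample(pools$content_low, nc, replace = TRUE),
                 sample(pools$content_high, nc, replace = TRUE))
        }
      } else {
        sample(c(pools$content_high, pools$content_low), nc, replace = TRUE)
      }
    }
    if (config$marker_rate > 0 && stats::runif(1) < config$marker_rate) {
      tag <- if (config$domain_specific) dom else "all"
      toks[sample.int(L, 1)] <- paste0(if (truthful) "veritok_" else "faltok_", tag)
    }
    extra <- character(0)
    if (stats::runif(1) < config$entity_noise) {
      cat <- sample(names(pools$entities), 1)
      extra <- c(extra, sample(pools$entities[[cat]]$base, 1))
    }
    if (truthful && nrow(ent_plants) > 0L) {
      for (j in seq_len(nrow(ent_plants))) {
        res <- pools$entities[[ent_plants$feature[j]]]$reserve
        extra <- c(extra, sample(res, min(ent_plants$delta[j], length(res))))
      }
    }
    assemble_text(c(toks, extra))
  }, character(1))

  corpus <- as_corpus(
    tibble::tibble(id = plan$id, subject_id = plan$subject_id,
                   domain = plan$domain, topic = "", veracity = plan$veracity,
                   text = texts),
    name = "synthetic", provenance = "veristyle synthetic generator"
  )

  truth <- tibble::tibble(feature = style_features(), planted = FALSE,
                          carrier = NA_character_, expected_shift = 0)
  if (nrow(pe) > 0L) {
    # expected percentage shift of a lexicon plant, accounting for the
    # other text components: content-word and marker overwrites, appended
    # entity words in the denominator, any planted length asymmetry, and
    # the Jensen correction for the random text length
    k_extra <- sum(ent_plants$delta)          # words appended to truthful
    # E[(L - overwrites) / (L + appended)] over the rounded, left-truncated
    # normal length distribution, mixing over the background-entity Bernoulli
    len_ratio <- function(mu, appended) {
      l <- 6:max(ceiling(mu + 8 * config$length_sd), 12)
      pl <- stats::pnorm(l + 0.5, mu, config$length_sd) -
        stats::pnorm(l - 0.5, mu, config$length_sd)
      pl[1] <- stats::pnorm(6.5, mu, config$length_sd)   # floor at six words
      pl <- pl / sum(pl)
      num <- l - config$n_content_words - config$marker_rate
      pn <- config$entity_noise
      sum(pl * ((1 - pn) * num / (l + appended) + pn * num / (l + appended + 1)))
    }
    lex_shift <- function(delta, b) {
      q <- delta / 100
      f_t <- len_ratio(config$length_mean + len_delta, k_extra)
      f_d <- len_ratio(config$length_mean, 0)
      (100 * q + b * (1 - q)) * f_t - b * f_d
    }
    for (j in seq_len(nrow(pe))) {
      f <- pe$feature[j]; row <- which(truth$feature == f)
      truth$planted[row] <- TRUE
      truth$carrier[row] <- pe$carrier[j]
      truth$expected_shift[row] <- switch(
        pe$carrier[j],
        lexicon = lex_shift(pe$delta[j], baseline_feature_pct(f, pools, lexicon)),
        length = pe$delta[j],
        entity = pe$delta[j],
        concreteness = pe$delta[j]
      )
    }
  }
  # entity carriers append words to truthful texts, so they co-shift the
  # length features; the ground truth records the arithmetic consequence
  ent_words <- sum(ent_plants$delta)
  if (ent_words > 0) {
    i <- truth$feature == "num_words"
    truth$expected_shift[i] <- truth$expected_shift[i] + ent_words
  }
  attr(truth, "pools") <- pools
  attr(truth, "carriers") <- carriers[intersect(names(carriers), pe$feature)]
  attr(truth, "markers") <- if (config$marker_rate > 0) {
    tags <- if (config$domain_specific) config$domains else "all"
    stats::setNames(lapply(tags, function(tg) {
      c(truthful = paste0("veritok_", tg), deceptive = paste0("faltok_", tg))
    }), tags)
  } else list()
  list(corpus = corpus, truth = truth)
}

mean_concreteness_pool <- function(words) {
  tbl <- read_concreteness(system.file("extdata", "fixture_concreteness.tsv",
                                       package = "veristyle", mustWork = TRUE))
  mean(tbl[words])
}

# join tokens into sentences of eight words, capitalized, period-terminated
assemble_text <- function(toks) {
  n <- length(toks)
  starts <- seq(1L, n, by = 8L)
  sent <- vapply(starts, function(s) {
    chunk <- toks[s:min(s + 7L, n)]
    substr(chunk[1], 1, 1) <- toupper(substr(chunk[1], 1, 1))
    paste0(paste(chunk, collapse = " "), ".")
  }, character(1))
  paste(sent, collapse = " ")
}

#' Compare realized class shifts against the generator's ground truth
#'
#' Extracts the style features of a generated corpus and returns, per
#' feature, the realized truthful-minus-deceptive mean difference, its
#' standard error, and the expected shift recorded at generation — the
#' oracle for parameter-recovery tests.
#'
#' @param corpus A generated `veristyle_corpus`.
#' @param truth The matching ground-truth tibble.
#' @param resources Extraction resources (default [fixture_resources()]).
#' @return Tibble `feature, planted, expected_shift, realized_shift, se`.
#' @export
planted_truth_check <- function(corpus, truth, resources = fixture_resources()) {
  feats <- extract_features(corpus, resources)
  purrr::map_dfr(style_features(), function(f) {
    x <- feats[[f]][feats$veracity == "truthful"]
    y <- feats[[f]][feats$veracity == "deceptive"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    row <- truth[truth$feature == f, ]
    tibble::tibble(
      feature = f, planted = row$planted,
      expected_shift = row$expected_shift,
      realized_shift = if (length(x) && length(y)) mean(x) - mean(y) else NA_real_,
      se = if (length(x) > 1L && length(y) > 1L) {
        sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
      } else NA_real_
    )
  })
}
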