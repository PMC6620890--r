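# Synthetic Spanish vocabulary bank.
#
# The generator emits token sequences, not grammatical Spanish; what matters is
# that every emitted word is resolvable by the dictionary tagger and by the
# relevant lexicons, and that the part-of-speech inventories are pairwise
# disjoint so category bookkeeping is exact. The inventories below are curated
# real Spanish words. Lexicon-annotated words (negation cues, emotion terms,
# polarity terms, depression keywords) each live in exactly one POS inventory.

POS_CATEGORIES <- c("noun", "verb", "pronoun", "adjective", "determiner",
                    "adverb", "adposition", "conjunction")

PRONOUN_PERSONS <- c("1S", "1P", "2S", "2P", "3S", "3P")

EMOTIONS <- c("happiness", "sadness", "anger", "fear", "disgust", "surprise")

# Personal pronoun forms by person/number, including clitic and object forms.
# "se" is mapped to 3S and "nos"/"os" to 1P/2P; "ustedes" to 2P.
PRONOUN_TABLE <- list(
  `1S` = c("yo", "me", "mí", "conmigo"),
  `1P` = c("nosotros", "nosotras", "nos"),
  `2S` = c("tú", "te", "ti", "vos", "usted"),
  `2P` = c("vosotros", "vosotras", "os", "ustedes"),
  `3S` = c("él", "ella", "ello", "se", "lo", "la", "le"),
  `3P` = c("ellos", "ellas", "los", "las", "les")
)

NONPERSONAL_PRONOUNS <- c("esto", "eso", "aquello", "algo", "alguien",
                          "quien", "cual", "otro", "demasiados")

# Negation cue list (the bundled default for detect_negations).
NEGATION_WORDS <- c("no", "nada", "nadie", "nunca", "jamás", "ni",
                    "ningún", "ninguno", "ninguna", "tampoco", "sin")

# Depression keyword list: screening seed terms with "/a" gender-variant
# markers. Expansion replaces the final "o" of the masculine form with "a".
DEPRESSION_KEYWORDS <- c(
  "agobiado/a", "agotado/a", "angustiado/a", "ansiedad", "ansioso/a",
  "cansado/a", "decaído", "depresión", "depresivo/a",
  "deprimido/a", "desanimado/a", "desesperado/a", "desmotivado/a",
  "insomnio", "llorar", "nervioso", "preocupado/a", "solo/a", "triste",
  "vacío/a"
)

# Profile-description derivations of "depr" used for user screening.
DEPR_DERIVATIONS <- c("depre", "depresión", "depresivo", "depresiva",
                      "deprimido", "deprimida")

# Emotion lexicon stand-in: term, emotion, POS of the term.
EMOTION_LEXICON_SYNTH <- tibble::tribble(
  ~term,            ~emotion,     ~pos,
  "alegría",   "happiness",  "noun",
  "felicidad",      "happiness",  "noun",
  "contento",       "happiness",  "adjective",
  "risa",           "happiness",  "noun",
  "tristeza",       "sadness",    "noun",
  "pena",           "sadness",    "noun",
  "melancolía","sadness",    "noun",
  "llanto",         "sadness",    "noun",
  "enojo",          "anger",      "noun",
  "rabia",          "anger",      "noun",
  "furioso",        "anger",      "adjective",
  "ira",            "anger",      "noun",
  "miedo",          "fear",       "noun",
  "temor",          "fear",       "noun",
  "pánico",    "fear",       "noun",
  "asustado",       "fear",       "adjective",
  "asco",           "disgust",    "noun",
  "repulsión", "disgust",    "noun",
  "repugnante",     "disgust",    "adjective",
  "náusea",    "disgust",    "noun",
  "sorpresa",       "surprise",   "noun",
  "asombro",        "surprise",   "noun",
  "asombrado",      "surprise",   "adjective",
  "inesperado",     "surprise",   "adjective"
)

# Binary polarity lexicon stand-in (+1 / -1), all adjectives.
POLARITY_BINARY_SYNTH <- tibble::tibble(
  term = c("bueno", "genial", "maravilloso", "excelente", "estupendo",
           "precioso", "fantástico", "agradable", "bonito", "perfecto",
           "encantador", "magnífico",
           "malo", "horrible", "terrible", "fatal", "espantoso", "odioso",
           "desagradable", "feo", "pésimo", "atroz", "lamentable",
           "nefasto"),
  value = rep(c(1, -1), each = 12)
)

# Graded polarity lexicon stand-in (values in [-1, 1]), all adjectives.
POLARITY_GRADED_SYNTH <- tibble::tibble(
  term = c("sublime", "glorioso", "espléndido", "radiante",
           "aceptable", "decente", "correcto", "apañado",
           "mediocre", "flojo", "soso", "insulso",
           "desastroso", "infame", "deplorable", "ruinoso"),
  value = c(rep(0.8, 4), rep(0.3, 4), rep(-0.3, 4), rep(-0.8, 4))
)

# Plain filler inventories (no lexicon annotation).
PLAIN_NOUNS <- c("casa", "tiempo", "vida", "día", "noche", "mundo",
                 "gente", "cosa", "año", "momento", "trabajo", "ciudad",
                 "amigo", "familia", "música", "foto", "juego", "libro",
                 "calle", "cielo", "mano", "corazón", "palabra",
                 "semana", "hora", "camino", "puerta", "mesa", "perro",
                 "gato")
PLAIN_VERBS <- c("ser", "estar", "tener", "hacer", "poder", "decir", "ir",
                 "ver", "dar", "saber", "querer", "llegar", "pasar", "deber",
                 "poner", "parecer", "quedar", "creer", "hablar", "llevar",
                 "dejar", "seguir", "encontrar", "llamar", "venir", "pensar",
                 "salir", "volver", "tomar", "conocer")
PLAIN_ADJECTIVES <- c("grande", "pequeño", "nuevo", "viejo", "joven",
                      "alto", "bajo", "largo", "corto", "fácil",
                      "difícil", "rápido", "lento", "claro",
                      "oscuro", "fuerte", "débil", "lleno", "abierto",
                      "cerrado")
DETERMINERS <- c("el", "un", "una", "unos", "unas", "este", "esta", "estos",
                 "estas", "ese", "esa", "aquel", "aquella", "mi", "su",
                 "mis", "sus", "cada", "alguna", "cualquier")
PLAIN_ADVERBS <- c("muy", "bien", "mal", "hoy", "ahora", "siempre",
                   "después", "antes", "aquí", "allí",
                   "así", "también", "ya", "casi", "luego",
                   "pronto", "tarde", "cerca", "lejos", "quizás")
ADPOSITIONS <- c("de", "a", "en", "con", "por", "para", "entre", "hasta",
                 "desde", "sobre", "tras", "durante", "mediante", "contra",
                 "hacia")
CONJUNCTIONS <- c("y", "o", "pero", "porque", "aunque", "cuando", "si",
                  "pues", "mientras", "sino", "como", "que")

#' Expand gender-variant keyword entries
#'
#' Entries carrying the "/a" marker ("agobiado/a") expand to both gendered
#' forms (agobiado, agobiada); plain entries map to themselves. Returns a
#' tibble with one row per surface form and its canonical entry.
#'
#' @param entries Character vector of keyword entries (lower-case).
#' @return A tibble with columns `form` and `canonical`.
#' @export
expand_keywords <- function(entries) {
  stopifnot(is.character(entries))
  purrr::map_dfr(entries, function(e) {
    if (grepl("/a$", e)) {
      masc <- sub("/a$", "", e)
      fem <- sub("o$", "a", masc)
      tibble(form = c(masc, fem), canonical = e)
    } else {
      tibble(form = e, canonical = e)
    }
  })
}

#' Build the synthetic vocabulary bank
#'
#' Assembles the per-category word inventories, the personal-pronoun table and
#' the lexicon-annotated word sets used by the corpus generator and the
#' bundled dictionary tagger. The bank content is fixed (curated); the seed
#' only fixes the (irrelevant) internal ordering, so any two calls agree.
#'
#' @param seed Integer seed (kept for interface stability; content does not
#'   depend on it).
#' @return An object of class `tv_vocabulary`: a list with `inventories`
#'   (named list of character vectors per POS category), `pronouns`
#'   (person -> forms), `nonpersonal_pronouns`, `negations`, `emotions`
#'   (tibble term/emotion), `polarity_binary`, `polarity_graded` (tibbles
#'   term/value), `keywords` (expanded tibble), and `tagged` (tibble
#'   word/pos/person covering every word in the bank).
#' @export
build_vocabulary <- function(seed = 1L) {
  kw <- expand_keywords(DEPRESSION_KEYWORDS)
  kw_nouns <- c("ansiedad", "depresión", "insomnio", "depre")
  kw_verbs <- "llorar"
  kw_adjs <- setdiff(kw$form, c(kw_nouns, kw_verbs))

  inv <- list(
    noun = unique(c(PLAIN_NOUNS, kw_nouns,
                    EMOTION_LEXICON_SYNTH$term[EMOTION_LEXICON_SYNTH$pos == "noun"])),
    verb = unique(c(PLAIN_VERBS, kw_verbs)),
    pronoun = unique(c(unlist(PRONOUN_TABLE, use.names = FALSE),
                       NONPERSONAL_PRONOUNS)),
    adjective = unique(c(
      PLAIN_ADJECTIVES, kw_adjs,
      EMOTION_LEXICON_SYNTH$term[EMOTION_LEXICON_SYNTH$pos == "adjective"],
      POLARITY_BINARY_SYNTH$term, POLARITY_GRADED_SYNTH$term)),
    determiner = DETERMINERS,
    adverb = unique(c(PLAIN_ADVERBS, NEGATION_WORDS)),
    adposition = ADPOSITIONS,
    conjunction = CONJUNCTIONS
  )

  overlap <- table(unlist(inv, use.names = FALSE))
  if (any(overlap > 1)) {
    abort(paste0("vocabulary inventories overlap: ",
                 paste(names(overlap)[overlap > 1], collapse = ", ")))
  }

  person_of <- unlist(lapply(names(PRONOUN_TABLE), function(p) {
    setNames(rep(p, length(PRONOUN_TABLE[[p]])), PRONOUN_TABLE[[p]])
  }))
  tagged <- purrr::map_dfr(names(inv), function(cat) {
    tibble(word = inv[[cat]], pos = cat,
           person = if (cat == "pronoun") unname(person_of[inv[[cat]]])
                    else NA_character_)
  })

  # Plain inventories carry no lexicon annotation: the generator draws its
  # base token stream from these, so every emotion/polarity/negation/keyword
  # occurrence in a synthetic tweet is an explicit, recorded injection.
  plain <- list(
    noun = PLAIN_NOUNS, verb = PLAIN_VERBS, adjective = PLAIN_ADJECTIVES,
    determiner = DETERMINERS, adverb = PLAIN_ADVERBS,
    adposition = ADPOSITIONS, conjunction = CONJUNCTIONS
  )

  structure(list(
    inventories = inv,
    plain = plain,
    pronouns = PRONOUN_TABLE,
    nonpersonal_pronouns = NONPERSONAL_PRONOUNS,
    negations = NEGATION_WORDS,
    emotions = EMOTION_LEXICON_SYNTH[, c("term", "emotion")],
    polarity_binary = POLARITY_BINARY_SYNTH,
    polarity_graded = POLARITY_GRADED_SYNTH,
    keywords = kw,
    tagged = tagged,
    seed = as.integer(seed)
  ), class = "tv_vocabulary")
}

#' Write the bank's lexicons and tagged vocabulary to plain-text files
#'
#' Emits the external-interface files (one-term-per-line lists and
#' term<TAB>annotation TSVs) that mirror the bundled `inst/extdata` resources.
#'
#' @param bank A `tv_vocabulary` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_vocabulary_files <- function(bank, dir) {
  stopifnot(inherits(bank, "tv_vocabulary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    keywords = file.path(dir, "depression_keywords.txt"),
    derivations = file.path(dir, "depr_derivations.txt"),
    negations = file.path(dir, "negations.txt"),
    tagged = file.path(dir, "tagged_vocabulary_synthetic.tsv"),
    emotions = file.path(dir, "emotion_lexicon_synthetic.tsv"),
    polarity_binary = file.path(dir, "polarity_binary_synthetic.tsv"),
    polarity_graded = file.path(dir, "polarity_graded_synthetic.tsv")
  )
  writeLines(DEPRESSION_KEYWORDS, paths["keywords"], useBytes = FALSE)
  writeLines(DEPR_DERIVATIONS, paths["derivations"])
  writeLines(bank$negations, paths["negations"])
  tg <- bank$tagged
  tg$person[is.na(tg$person)] <- ""
  utils::write.table(tg, paths["tagged"], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(bank$emotions, paths["emotions"], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(bank$polarity_binary, paths["polarity_binary"],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  utils::write.table(bank$polarity_graded, paths["polarity_graded"],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(paths)
}
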