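# Builtin Spanish stopword list: high-frequency function words (articles,
# prepositions, pronouns, conjunctions, common auxiliaries and adverbs).
# Stored accent-free and lowercase because stopword filtering runs after
# accent stripping in the normalization pipeline.

spanish_stopwords_builtin <- c(
  "a", "al", "algo", "algunas", "algunos", "ante", "antes", "aquel",
  "aquella", "aquellas", "aquellos", "aqui", "asi", "aun", "aunque",
  "cada", "como", "con", "contra", "cual", "cuales", "cuando", "de",
  "del", "desde", "donde", "dos", "durante", "e", "el", "ella", "ellas",
  "ellos", "en", "entonces", "entre", "era", "erais", "eran", "eras",
  "eres", "es", "esa", "esas", "ese", "eso", "esos", "esta", "estaba",
  "estaban", "estamos", "estan", "estar", "estas", "este", "esto",
  "estos", "estoy", "fue", "fueron", "fui", "ha", "habia", "habian",
  "han", "has", "hasta", "hay", "he", "la", "las", "le", "les", "lo",
  "los", "luego", "mas", "me", "mi", "mia", "mias", "mientras", "mis",
  "mismo", "mucha", "muchas", "mucho", "muchos", "muy", "nada", "ni",
  "no", "nos", "nosotras", "nosotros", "nuestra", "nuestras", "nuestro",
  "nuestros", "o", "os", "otra", "otras", "otro", "otros", "para",
  "pero", "poco", "por", "porque", "pues", "que", "quien", "quienes",
  "se", "sea", "sean", "segun", "ser", "si", "sido", "siendo", "sin",
  "sobre", "somos", "son", "soy", "su", "sus", "suya", "suyas", "suyo",
  "suyos", "tal", "tambien", "tan", "tanto", "te", "tenia", "tiene",
  "tienen", "toda", "todas", "todo", "todos", "tras", "tu", "tus", "un",
  "una", "unas", "uno", "unos", "usted", "ustedes", "vosotras",
  "vosotros", "vuestra", "vuestras", "vuestro", "vuestros", "y", "ya",
  "yo"
)

#' Builtin stopword lists
#'
#' @param language currently only `"spanish"`.
#' @return A character vector of lowercase, accent-free stopwords.
#' @export
prsf_stopwords <- function(language = "spanish") {
  language <- match.arg(language, "spanish")
  spanish_stopwords_builtin
}
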