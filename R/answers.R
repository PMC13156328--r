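#' Tagged answer values
#'
#' Every question in the benchmark carries a canonical ground-truth answer
#' represented as a tagged value: a count, a label token, a yes/no flag, a
#' token set, an ordered token sequence, a 2D box, a 2D/3D point, a scalar
#' with units, a list of scene-graph triplets, or free text. The tag decides
#' both the serialization and the scoring rule applied to the task.
#'
#' @param value payload appropriate for the tag (see individual constructors)
#' @name answer-values
NULL

new_answer <- function(tag, value, units = NULL) {
  structure(list(tag = tag, value = value, units = units),
            class = "orqa_answer")
}

#' @rdname answer-values
#' @export
answer_count <- function(value) {
  stopifnot(length(value) == 1L, is.finite(value), value >= 0)
  new_answer("count", as.integer(round(value)))
}

#' @rdname answer-values
#' @export
answer_label <- function(value) {
  new_answer("label", norm_token(value))
}

#' @rdname answer-values
#' @export
answer_binary <- function(value) {
  if (is.logical(value)) value <- if (value) "yes" else "no"
  value <- norm_token(value)
  stopifnot(value %in% c("yes", "no"))
  new_answer("binary", value)
}

#' @rdname answer-values
#' @export
answer_set <- function(value) {
  new_answer("set", sort(unique(norm_token(value))))
}

#' @rdname answer-values
#' @export
answer_sequence <- function(value) {
  new_answer("sequence", norm_token(value))
}

#' @rdname answer-values
#' @export
answer_box <- function(value) {
  value <- as.numeric(value)
  stopifnot(length(value) == 4L, all(is.finite(value)))
  new_answer("box", round(value))
}

#' @rdname answer-values
#' @export
answer_point2 <- function(value) {
  value <- as.numeric(value)
  stopifnot(length(value) == 2L, all(is.finite(value)))
  new_answer("point2", round(value, 1), units = "px")
}

#' @rdname answer-values
#' @export
answer_point3 <- function(value) {
  value <- as.numeric(value)
  stopifnot(length(value) == 3L, all(is.finite(value)))
  new_answer("point3", round(value, 2), units = "m")
}

#' @rdname answer-values
#' @param units one of `"m"`, `"s"`, `"percent"`
#' @export
answer_scalar <- function(value, units) {
  stopifnot(length(value) == 1L, is.finite(value),
            units %in% c("m", "s", "percent"))
  digits <- switch(units, m = 2L, s = 0L, percent = 0L)
  new_answer("scalar", round(as.numeric(value), digits), units = units)
}

#' @rdname answer-values
#' @export
answer_triplets <- function(value) {
  # value: list of length-3 character vectors (subject, predicate, object)
  trips <- lapply(value, function(tr) {
    stopifnot(length(tr) == 3L)
    norm_token(tr)
  })
  new_answer("triplets", trips)
}

#' @rdname answer-values
#' @export
answer_text <- function(value) {
  new_answer("text", norm_text(value))
}

answer_parse_failure <- function(raw = "") {
  structure(list(tag = "parse_failure", value = NULL, units = NULL,
                 raw = as.character(raw)[1]),
            class = "orqa_answer")
}

#' @export
print.orqa_answer <- function(x, ...) {
  cat(sprintf("<orqa_answer %s> %s\n", x$tag, serialize_answer(x)))
  invisible(x)
}

# Token normalization: case-fold, trim, strip flanking punctuation, collapse
# internal whitespace to underscores so "Head surgeon" matches "head_surgeon".
norm_token <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x)
  gsub("[[:space:]]+", "_", x)
}

# Free-text normalization for BLEU-style scoring: case-fold, squeeze spaces.
norm_text <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

fmt_num <- function(x) {
  # plain decimal notation, no trailing zeros beyond what round() kept
  sub("\\.?0+$", "", sprintf("%.6f", x))
}

#' Serialize an answer to its canonical text form
#'
#' The canonical form is what ground-truth files store and what
#' [parse_answer()] inverts: counts and scalars as plain decimal numbers,
#' sets/sequences comma-separated (sets sorted; the empty set is `"none"`),
#' boxes as `"x1,y1,x2,y2"`, points comma-separated, triplets as
#' `"(s,p,o); (s,p,o)"`.
#'
#' @param answer an `orqa_answer`
#' @return a single character string
#' @export
serialize_answer <- function(answer) {
  stopifnot(inherits(answer, "orqa_answer"))
  v <- answer$value
  switch(answer$tag,
    count = as.character(v),
    label = v,
    binary = v,
    set = if (length(v) == 0L) "none" else paste(v, collapse = ", "),
    sequence = if (length(v) == 0L) "none" else paste(v, collapse = ", "),
    box = paste(fmt_num(v), collapse = ","),
    point2 = paste(fmt_num(v), collapse = ","),
    point3 = paste(fmt_num(v), collapse = ","),
    scalar = fmt_num(v),
    triplets = if (length(v) == 0L) "none" else
      paste(vapply(v, function(tr) sprintf("(%s)", paste(tr, collapse = ",")),
                   ""), collapse = "; "),
    text = v,
    parse_failure = answer$raw,
    stop("unknown answer tag: ", answer$tag)
  )
}

extract_numbers <- function(text, n) {
  m <- gregexpr("-?[0-9]*\\.?[0-9]+", text)[[1]]
  if (m[1] == -1L) return(NULL)
  nums <- as.numeric(regmatches(text, list(m))[[1]])
  if (length(nums) < n) return(NULL)
  nums[seq_len(n)]
}

split_tokens <- function(text) {
  text <- gsub("^[\\[\\{\\(]+|[\\]\\}\\)]+$", "", trimws(text), perl = TRUE)
  parts <- unlist(strsplit(text, "(,|;| and )", perl = TRUE))
  parts <- norm_token(parts)
  parts[nzchar(parts)]
}

#' Parse free text into a tagged answer
#'
#' Lenient parser used both to read back canonical ground truth and to
#' interpret model output. Case and flanking punctuation are ignored; lists
#' may be separated by commas, semicolons, or "and"; boxes and points accept
#' any text containing the right number of numbers; scalars take the leading
#' number, ignoring units text ("approximately 1.8 meters" parses as 1.8).
#' Failures never raise: they yield an answer with tag `"parse_failure"`
#' which every scoring rule maps to 0.
#'
#' @param text character string to parse
#' @param task task id (decides the expected answer tag) — see [orqa_tasks()]
#' @param strict if `TRUE`, only the canonical serialization is accepted
#' @return an `orqa_answer`
#' @export
parse_answer <- function(text, task, strict = FALSE) {
  tag <- task_answer_tag(task)
  units <- task_units(task)
  text <- as.character(text)[1]
  if (is.na(text) || !nzchar(trimws(text))) return(answer_parse_failure(text))
  out <- tryCatch(parse_by_tag(text, tag, units, strict),
                  error = function(e) NULL)
  if (is.null(out)) answer_parse_failure(text) else out
}

parse_by_tag <- function(text, tag, units, strict) {
  switch(tag,
    count = {
      v <- extract_numbers(text, 1L)
      if (is.null(v) || v < 0 || (strict && v != round(v))) return(NULL)
      answer_count(v)
    },
    label = {
      v <- norm_token(text)
      if (!nzchar(v)) return(NULL)
      answer_label(v)
    },
    binary = {
      tok <- norm_token(strsplit(trimws(text), "[[:space:],.!]+")[[1]][1])
      if (tok %in% c("yes", "y", "true")) answer_binary("yes")
      else if (tok %in% c("no", "n", "false")) answer_binary("no")
      else NULL
    },
    set = {
      toks <- split_tokens(text)
      if (length(toks) == 1L && toks == "none") toks <- character(0)
      answer_set(toks)
    },
    sequence = {
      toks <- split_tokens(text)
      if (length(toks) == 1L && toks == "none") toks <- character(0)
      answer_sequence(toks)
    },
    box = {
      v <- extract_numbers(text, 4L)
      if (is.null(v)) return(NULL)
      answer_box(v)
    },
    point2 = {
      v <- extract_numbers(text, 2L)
      if (is.null(v)) return(NULL)
      answer_point2(v)
    },
    point3 = {
      v <- extract_numbers(text, 3L)
      if (is.null(v)) return(NULL)
      answer_point3(v)
    },
    scalar = {
      v <- extract_numbers(text, 1L)
      if (is.null(v)) return(NULL)
      answer_scalar(v, units)
    },
    triplets = {
      if (norm_token(text) == "none") return(answer_triplets(list()))
      m <- gregexpr("\\(([^()]*)\\)", text)[[1]]
      chunks <- if (m[1] != -1L) {
        gsub("^\\(|\\)$", "", regmatches(text, list(m))[[1]])
      } else {
        unlist(strsplit(text, ";"))
      }
      trips <- lapply(chunks, function(ch) {
        parts <- norm_token(strsplit(ch, ",")[[1]])
        parts[nzchar(parts)]
      })
      trips <- Filter(function(p) length(p) == 3L, trips)
      if (length(trips) == 0L) return(NULL)
      answer_triplets(trips)
    },
    text = answer_text(text),
    stop("unknown tag: ", tag)
  )
}

#' Compare two answers for canonical equality
#'
#' Numeric payloads are compared within 1e-9; sets ignore order; triplet
#' lists ignore order of triplets.
#'
#' @param a,b `orqa_answer` objects
#' @return `TRUE` or `FALSE`
#' @export
answer_equal <- function(a, b) {
  stopifnot(inherits(a, "orqa_answer"), inherits(b, "orqa_answer"))
  if (a$tag != b$tag) return(FALSE)
  if (a$tag == "parse_failure") return(FALSE)
  v1 <- a$value; v2 <- b$value
  num_eq <- function(x, y) length(x) == length(y) && all(abs(x - y) < 1e-9)
  switch(a$tag,
    count = v1 == v2,
    label = , binary = , text = identical(v1, v2),
    set = identical(sort(v1), sort(v2)),
    sequence = identical(v1, v2),
    box = , point2 = , point3 = num_eq(v1, v2),
    scalar = num_eq(v1, v2) && identical(a$units, b$units),
    triplets = {
      key <- function(v) sort(vapply(v, paste, "", collapse = "|"))
      identical(key(v1), key(v2))
    }
  )
}
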