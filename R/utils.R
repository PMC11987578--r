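# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# coded condition so callers/tests can match on the code, not message wording
stop_cc <- function(code, fmt, ...) {
  msg <- sprintf("[%s] %s", code, sprintf(fmt, ...))
  cond <- structure(
    class = c("cc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), code = code)
  )
  stop(cond)
}

# stratum key: geographic domain x facility category
st_key <- function(geo_domain, facility_category) {
  paste(geo_domain, facility_category, sep = "\x1f")
}

# weighted mean with positive-weight guard
wmean <- function(x, w) {
  sw <- sum(w)
  if (sw <= 0) stop_cc("zero-weight", "total weight is not positive")
  sum(w * x) / sw
}

# split semicolon-delimited source strings into a list of code vectors
split_sources <- function(sources) {
  out <- strsplit(ifelse(is.na(sources), "", sources), ";", fixed = TRUE)
  lapply(out, function(s) {
    s <- trimws(s)
    s[nzchar(s)]
  })
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

finding <- function(code, location, message) {
  data.frame(code = code, location = location, message = message,
             stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(code = character(), location = character(), message = character(),
             stringsAsFactors = FALSE)
}

# n x length(names) matrix with column j filled by f(names[j]); keeps matrix
# shape even for a single row or a single column
vmat <- function(names, n, f) {
  m <- matrix(0, n, length(names), dimnames = list(NULL, names))
  for (j in seq_along(names)) m[, j] <- f(names[j])
  m
}

# columns of `df` with the given prefix, as a numeric matrix named by item code
item_matrix <- function(df, prefix) {
  cols <- grep(paste0("^", prefix), names(df), value = TRUE)
  codes <- sub(paste0("^", prefix), "", cols)
  m <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  colnames(m) <- codes
  m
}
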