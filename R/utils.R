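# Shared infrastructure: classed error conditions, stderr logging,
# population-path handling and round-trip numeric serialization.

# Every user-facing failure carries a stable machine-readable token
# (surfaced by the CLI as "<TOKEN>: message") plus an R condition class
# "cyto_<lowercase token>" so callers can use tryCatch on either.
cytoStop <- function(token, msg, call. = FALSE) {
  cls <- paste0("cyto_", tolower(token))
  stop(structure(
    class = c(cls, "cytoError", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL,
         token = token)
  ))
}

#' Extract the machine-readable error class token from a condition
#'
#' @param cond a condition object, typically caught with `tryCatch()`.
#' @return A single string such as `"UNSUPPORTED_EXPORT"`, or
#'   `"INTERNAL"` for conditions not raised by this package.
#' @export
errorToken <- function(cond) {
  if (!is.null(cond$token)) cond$token else "INTERNAL"
}

.logLevels <- c(ERROR = 1L, INFO = 2L, DEBUG = 3L)

#' Set the package log level
#'
#' Provenance decisions (which compensation matrix was auto-selected,
#' when default transform parameters were substituted, raw-to-transformed
#' gate coordinate conversions) are logged to stderr at level INFO.
#'
#' @param level one of `"ERROR"`, `"INFO"`, `"DEBUG"`.
#' @return The previous level, invisibly.
#' @export
cytoLogLevel <- function(level = c("ERROR", "INFO", "DEBUG")) {
  level <- match.arg(level)
  old <- getOption("cytoBridge.logLevel", "ERROR")
  options(cytoBridge.logLevel = level)
  invisible(old)
}

cytoLog <- function(level, ...) {
  cur <- getOption("cytoBridge.logLevel", "ERROR")
  if (.logLevels[[level]] <= .logLevels[[cur]])
    cat(sprintf("[%s] %s\n", level, paste0(...)), file = stderr())
  invisible(NULL)
}

# ---- population paths -------------------------------------------------

# Canonical form: "root", "root/lymph", "root/lymph/CD3". Accepts a
# leading "/" and an omitted root segment. Names may contain spaces,
# never "/".
normPopPath <- function(path) {
  stopifnot(is.character(path))
  if (!length(path)) return(character(0))
  p <- sub("^/+", "", path)
  p <- sub("/+$", "", p)
  ifelse(p == "" | p == "root", "root",
         ifelse(startsWith(p, "root/"), p, paste0("root/", p)))
}

popParentPath <- function(path) {
  path <- normPopPath(path)
  ifelse(path == "root", NA_character_,
         vapply(path, function(p) {
           parts <- strsplit(p, "/", fixed = TRUE)[[1]]
           paste(parts[-length(parts)], collapse = "/")
         }, character(1), USE.NAMES = FALSE))
}

popName <- function(path) {
  path <- normPopPath(path)
  vapply(strsplit(path, "/", fixed = TRUE), function(x) x[length(x)],
         character(1))
}

# ---- numbers ----------------------------------------------------------

# 17 significant digits: doubles survive text round-trips bit-exactly.
fmtNum <- function(x) sprintf("%.17g", as.numeric(x))

parseNum <- function(s) as.numeric(s)
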