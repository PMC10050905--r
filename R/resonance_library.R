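# Resonance library: per-moiety 1H/13C library shifts and 13C-13C
# J-coupling constants driving search windows and multiplet simulation.

#' Construct a single resonance library entry
#'
#' One entry describes one proton resonance of a CH moiety: its library
#' chemical shifts and the scalar couplings of its carbon to neighbouring
#' carbons.  Diastereotopic protons on the same carbon (e.g. C3a / C3b)
#' are separate entries sharing `delta_c_lib` and `couplings`.
#'
#' @param metabolite Metabolite name (lower case recommended).
#' @param moiety Carbon label with optional proton sub-label, e.g. `"C2"`,
#'   `"C3a"`.
#' @param delta_h_lib,delta_c_lib Library chemical shifts in ppm;
#'   `0 <= delta_h_lib <= 13`, `0 <= delta_c_lib <= 220`.
#' @param couplings Data frame with columns `partner` (character), `j`
#'   (Hz, > 0) and `one_bond` (logical).
#' @return An object of class `resonance_entry`.
#' @export
resonance_entry <- function(metabolite, moiety, delta_h_lib, delta_c_lib,
                            couplings = data.frame(partner = character(),
                                                   j = numeric(),
                                                   one_bond = logical())) {
  if (!(delta_h_lib >= 0 && delta_h_lib <= 13)) {
    stop("delta_h_lib out of range [0, 13] for ", metabolite, " ", moiety,
         call. = FALSE)
  }
  if (!(delta_c_lib >= 0 && delta_c_lib <= 220)) {
    stop("delta_c_lib out of range [0, 220] for ", metabolite, " ", moiety,
         call. = FALSE)
  }
  stopifnot(is.data.frame(couplings),
            all(c("partner", "j", "one_bond") %in% names(couplings)))
  if (nrow(couplings) && any(couplings$j <= 0)) {
    stop("non-positive J coupling in entry ", metabolite, " ", moiety,
         call. = FALSE)
  }
  structure(list(metabolite = as.character(metabolite),
                 moiety = as.character(moiety),
                 delta_h_lib = as.numeric(delta_h_lib),
                 delta_c_lib = as.numeric(delta_c_lib),
                 couplings = couplings),
            class = "resonance_entry")
}

#' @export
print.resonance_entry <- function(x, ...) {
  cpl <- if (nrow(x$couplings)) {
    paste(sprintf("%s:%.1f%s", x$couplings$partner, x$couplings$j,
                  ifelse(x$couplings$one_bond, "", " (long-range)")),
          collapse = ", ")
  } else "none"
  cat(sprintf("<resonance_entry> %s %s  1H %.3f ppm  13C %.2f ppm  J: %s\n",
              x$metabolite, x$moiety, x$delta_h_lib, x$delta_c_lib, cpl))
  invisible(x)
}

parse_couplings <- function(text) {
  text <- trimws(text)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(partner = character(), j = numeric(),
                      one_bond = logical()))
  }
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  rows <- lapply(parts, function(p) {
    f <- trimws(strsplit(p, ":", fixed = TRUE)[[1]])
    if (length(f) < 2L || length(f) > 3L || is.na(suppressWarnings(as.numeric(f[2])))) {
      stop("malformed coupling field '", p, "'", call. = FALSE)
    }
    data.frame(partner = f[1], j = as.numeric(f[2]),
               one_bond = !(length(f) == 3L && f[3] == "long"))
  })
  do.call(rbind, rows)
}

#' Load a resonance library from file
#'
#' The library file is CSV with one record per proton resonance and
#' columns `metabolite, moiety, delta_h, delta_c, couplings`; the
#' `couplings` field lists `partner:J` pairs in Hz separated by `;`, with
#' an optional `:long` suffix marking long-range (more than one bond)
#' couplings.  Lines starting with `#` are comments; the first such line
#' conventionally carries the format version.
#'
#' @param path Library file path.  The default is the library shipped with
#'   the package, which covers the CH resonances of lactate, alanine,
#'   glutamate and aspartate with shifts and one-bond couplings compiled
#'   from public references (HMDB / BMRB).
#' @return An object of class `resonance_library`.
#' @export
load_library <- function(path = default_library_path()) {
  if (!file.exists(path)) stop("library file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(body)) {
    warning("empty resonance library: ", path)
    return(structure(list(entries = list(), path = path),
                     class = "resonance_library"))
  }
  df <- utils::read.csv(text = paste(lines[body], collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("metabolite", "moiety", "delta_h", "delta_c", "couplings")
  if (!all(need %in% names(df))) {
    stop("library file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  line_of <- which(body)[-1L]  # data lines, after the header line
  entries <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    entries[[i]] <- tryCatch(
      resonance_entry(df$metabolite[i], df$moiety[i], df$delta_h[i],
                      df$delta_c[i], parse_couplings(df$couplings[i])),
      error = function(e) {
        stop("library record at line ",
             if (i <= length(line_of)) line_of[i] else i, ": ",
             conditionMessage(e), call. = FALSE)
      })
  }
  keys <- vapply(entries, function(e) paste(e$metabolite, e$moiety), "")
  if (anyDuplicated(keys)) {
    stop("duplicate (metabolite, moiety) entries: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(entries = entries, path = path),
            class = "resonance_library")
}

#' Path of the shipped default resonance library
#' @return File path of the packaged library CSV.
#' @export
default_library_path <- function() {
  system.file("extdata", "default_library.csv", package = "hsqcmult",
              mustWork = TRUE)
}

#' @export
print.resonance_library <- function(x, ...) {
  cat(sprintf("<resonance_library> %d entries (%s)\n", length(x$entries),
              basename(x$path)))
  for (e in x$entries) print(e)
  invisible(x)
}

#' List the resonance entries of one metabolite
#'
#' Returns all proton resonances of a metabolite in deterministic order
#' (sorted by moiety label); diastereotopic protons appear as separate
#' entries.
#'
#' @param library A [load_library()] result.
#' @param metabolite Metabolite name (matched case-insensitively).
#' @return List of [resonance_entry()] objects.
#' @export
resonances_of <- function(library, metabolite) {
  stopifnot(inherits(library, "resonance_library"))
  names_all <- vapply(library$entries, function(e) e$metabolite, "")
  hit <- tolower(names_all) == tolower(metabolite)
  if (!any(hit)) {
    near <- unique(names_all[agrepl(metabolite, names_all,
                                    ignore.case = TRUE, max.distance = 0.3)])
    stop("unknown metabolite '", metabolite, "'",
         if (length(near)) paste0("; did you mean: ",
                                  paste(near, collapse = ", "), "?") else "",
         call. = FALSE)
  }
  ent <- library$entries[hit]
  ent[order(vapply(ent, function(e) e$moiety, ""))]
}
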