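# Standard DNA Damage (SDD) style interchange.
#
# A plain-text damage-record format in the spirit of the community SDD
# specification: a key/value header terminated by ***EndOfHeader***,
# then one line per damage cluster with semicolon-separated fields. The
# field set here is the subset this chain produces; files round-trip
# through the bundled reader.

sdd_fields <- c("primary_id", "chromosome", "start_bp", "end_bp", "class",
                "n_breaks", "n_direct", "n_indirect", "source")

sdd_header_info <- function(cfg, model = NULL) {
  list(
    "SDD version" = "radbreak-subset-1.0",
    "Software" = paste("radbreak", utils::packageVersion("radbreak")),
    "Genome size bp" = if (!is.null(model)) count_genome_bp(model) else NA,
    "Cell model" = paste0("ellipsoid nucleus ",
                          paste(cfg$geometry$nucleus_semi_axes_um,
                                collapse = "x"), " um"),
    "Chromosomes" = cfg$geometry$chromosomes,
    "Particle" = cfg$beam$particle,
    "LET keV/um" = cfg$beam$let_keV_um,
    "Primaries" = cfg$beam$n_primaries,
    "Damage definition" = paste0("d_DSB=", cfg$damage$d_DSB_bp,
                                 "bp d_s=", cfg$damage$d_s_bp, "bp"))
}

#' Write damage clusters to an SDD-style file
#'
#' @param tally a `damage_tally` whose `clusters` are written, or a
#'   cluster data frame directly.
#' @param header named list of header fields (see the `Details`); any
#'   content is allowed.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdd <- function(tally, header, path) {
  clusters <- if (inherits(tally, "damage_tally")) tally$clusters else tally
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(header))
    writeLines(sprintf("%s, %s;", key, format(header[[key]])), con)
  writeLines("***EndOfHeader***;", con)
  if (!is.null(clusters) && nrow(clusters)) {
    if (!"primary_id" %in% names(clusters)) clusters$primary_id <- 0L
    if (!"chromosome" %in% names(clusters)) clusters$chromosome <- NA_integer_
    writeLines(sprintf("%d; %d; %d; %d; %s; %d; %d; %d; %s;",
                       clusters$primary_id, clusters$chromosome,
                       clusters$start_bp, clusters$end_bp, clusters$class,
                       clusters$n_breaks, clusters$n_direct,
                       clusters$n_indirect, clusters$source), con)
  }
  invisible(path)
}

#' Read an SDD-style damage file
#'
#' @param path file written by [write_sdd()].
#' @return list: `header` (named character list) and `clusters` data
#'   frame.
#' @export
read_sdd <- function(path) {
  lines <- readLines(path)
  end <- which(lines == "***EndOfHeader***;")
  if (length(end) != 1) stop("not an SDD file (no header terminator): ", path)
  header <- list()
  for (ln in lines[seq_len(end - 1)]) {
    parts <- strsplit(sub(";\\s*$", "", ln), ",", fixed = TRUE)[[1]]
    header[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = ","))
  }
  body <- lines[-seq_len(end)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    clusters <- data.frame(primary_id = integer(), chromosome = integer(),
                           start_bp = integer(), end_bp = integer(),
                           class = character(), n_breaks = integer(),
                           n_direct = integer(), n_indirect = integer(),
                           source = character())
  } else {
    m <- do.call(rbind, strsplit(sub(";\\s*$", "", body), ";"))
    m <- apply(m, 2, trimws)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    clusters <- data.frame(primary_id = as.integer(m[, 1]),
                           chromosome = as.integer(m[, 2]),
                           start_bp = as.integer(m[, 3]),
                           end_bp = as.integer(m[, 4]),
                           class = m[, 5],
                           n_breaks = as.integer(m[, 6]),
                           n_direct = as.integer(m[, 7]),
                           n_indirect = as.integer(m[, 8]),
                           source = m[, 9])
  }
  list(header = header, clusters = clusters)
}
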