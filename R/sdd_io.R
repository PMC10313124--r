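#' SDD file header
#'
#' Construct the header block for a Standard DNA Damage (SDD) file in the
#' minimal dialect read and written by this package. The dialect keeps the
#' key/value header block of SDD v1.0 (one `Key, value;` line per entry,
#' terminated by the `***EndOfHeader***;` sentinel) and the fields the model
#' consumes; any other header key is carried through verbatim in
#' `free_fields`.
#'
#' @param simulator_name Name of the software that produced the damage data.
#' @param dose_or_fluence Numeric exposure value, or `NA` if unknown.
#' @param dose_unit Unit of `dose_or_fluence`: `"Gy"` (dose) or `"/um2"`
#'   (fluence).
#' @param particle Free-text particle description (e.g. `"proton"`).
#' @param energy_MeV Primary particle energy in MeV, or `NA`.
#' @param site_definition_bp Length of a damage site in base pairs; the SDD
#'   convention (and this model) uses 10.
#' @param free_fields Named list of unparsed header keys, values kept as raw
#'   text.
#' @return An object of class `sdd_header`.
#' @seealso [read_sdd()], [write_sdd()]
#' @export
sdd_header <- function(simulator_name = "microgamma",
                       dose_or_fluence = NA_real_,
                       dose_unit = c("Gy", "/um2"),
                       particle = NA_character_,
                       energy_MeV = NA_real_,
                       site_definition_bp = 10L,
                       free_fields = list()) {
  dose_unit <- match.arg(dose_unit)
  site_definition_bp <- as.integer(site_definition_bp)
  if (is.na(site_definition_bp) || site_definition_bp < 1L)
    stop("site_definition_bp must be an integer >= 1", call. = FALSE)
  structure(
    list(
      simulator_name = as.character(simulator_name),
      dose_or_fluence = as.numeric(dose_or_fluence),
      dose_unit = dose_unit,
      particle = as.character(particle),
      energy_MeV = as.numeric(energy_MeV),
      site_definition_bp = site_definition_bp,
      free_fields = free_fields
    ),
    class = "sdd_header"
  )
}

#' @export
print.sdd_header <- function(x, ...) {
  cat("SDD header (minimal dialect)\n")
  cat("  simulator:     ", x$simulator_name, "\n")
  cat("  exposure:      ", x$dose_or_fluence, x$dose_unit, "\n")
  cat("  particle:      ", x$particle, "@", x$energy_MeV, "MeV\n")
  cat("  site length:   ", x$site_definition_bp, "bp\n")
  if (length(x$free_fields))
    cat("  free fields:   ", paste(names(x$free_fields), collapse = ", "), "\n")
  invisible(x)
}

#' Damage-site records
#'
#' Build and validate a table of 10-bp damage-site records, the in-memory
#' representation of the SDD data section. One row is one damage site:
#' lesion counts per strand and for bases, the double-strand-break flag, and
#' (optionally) how many of the site's lesions were caused by the direct
#' vs. the indirect (radical-mediated) effect.
#'
#' Genomic positions are 0-based site-start indices; spatial positions are
#' in micrometres in a nucleus-centered frame.
#'
#' If `has_dsb` is `NA` it is derived from the strand-break counts: a site
#' holds a DSB when both strands carry at least one break within the site.
#'
#' @param track_id Integer id of the primary-particle track.
#' @param chromosome_id Integer chromosome id.
#' @param genomic_position_bp Integer site start, base pairs, 0-based.
#' @param x_um,y_um,z_um Site position, micrometres, nucleus-centered.
#' @param n_sb_strand1,n_sb_strand2 Strand-break counts on each strand.
#' @param n_bd Base-damage count.
#' @param has_dsb Logical DSB flag, or `NA` to derive from strand counts.
#' @param cause_direct,cause_indirect Lesions attributed to the direct /
#'   indirect effect; both `NA` when cause information is absent.
#' @return A `data.frame` of class `damage_sites`.
#' @export
damage_sites <- function(track_id, chromosome_id = 1L, genomic_position_bp = 0L,
                         x_um = 0, y_um = 0, z_um = 0,
                         n_sb_strand1 = 0L, n_sb_strand2 = 0L, n_bd = 0L,
                         has_dsb = NA, cause_direct = NA_integer_,
                         cause_indirect = NA_integer_) {
  n <- length(track_id)
  df <- data.frame(
    track_id = as.integer(track_id),
    chromosome_id = rep_len(as.integer(chromosome_id), n),
    genomic_position_bp = rep_len(as.integer(genomic_position_bp), n),
    x_um = rep_len(as.numeric(x_um), n),
    y_um = rep_len(as.numeric(y_um), n),
    z_um = rep_len(as.numeric(z_um), n),
    n_sb_strand1 = rep_len(as.integer(n_sb_strand1), n),
    n_sb_strand2 = rep_len(as.integer(n_sb_strand2), n),
    n_bd = rep_len(as.integer(n_bd), n),
    has_dsb = rep_len(as.logical(has_dsb), n),
    cause_direct = rep_len(as.integer(cause_direct), n),
    cause_indirect = rep_len(as.integer(cause_indirect), n)
  )
  derive <- is.na(df$has_dsb)
  df$has_dsb[derive] <- df$n_sb_strand1[derive] >= 1L & df$n_sb_strand2[derive] >= 1L
  class(df) <- c("damage_sites", "data.frame")
  validate_damage_sites(df)
}

#' @rdname damage_sites
#' @param records A `damage_sites` data frame to validate.
#' @export
validate_damage_sites <- function(records) {
  req <- c("track_id", "chromosome_id", "genomic_position_bp",
           "x_um", "y_um", "z_um", "n_sb_strand1", "n_sb_strand2", "n_bd",
           "has_dsb", "cause_direct", "cause_indirect")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("damage_sites is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  counts <- records[c("n_sb_strand1", "n_sb_strand2", "n_bd")]
  if (any(unlist(counts) < 0L, na.rm = TRUE))
    stop("lesion counts must be non-negative", call. = FALSE)
  if (any(records$genomic_position_bp < 0L))
    stop("genomic positions must be >= 0", call. = FALSE)
  total <- records$n_sb_strand1 + records$n_sb_strand2 + records$n_bd
  if (any(total < 1L))
    stop("every damage site must contain at least one lesion", call. = FALSE)
  bad_dsb <- records$has_dsb &
    (records$n_sb_strand1 < 1L | records$n_sb_strand2 < 1L)
  if (any(bad_dsb))
    stop("has_dsb = TRUE requires at least one strand break on each strand",
         call. = FALSE)
  has_cause <- !is.na(records$cause_direct) & !is.na(records$cause_indirect)
  bad_cause <- has_cause &
    (records$cause_direct + records$cause_indirect != total)
  if (any(bad_cause))
    stop("cause_direct + cause_indirect must equal the total lesion count",
         call. = FALSE)
  if (!inherits(records, "damage_sites"))
    class(records) <- c("damage_sites", class(records))
  records
}

.sdd_sentinel <- "***EndOfHeader***;"

.sdd_known_keys <- c(
  "SDD version"       = "sdd_version",
  "Software"          = "simulator_name",
  "Dose or fluence"   = "dose_or_fluence",
  "Particle"          = "particle",
  "Energy"            = "energy_MeV",
  "Damage definition" = "site_definition_bp"
)

#' Read a Standard DNA Damage (SDD) file
#'
#' Parses the minimal SDD dialect written by [write_sdd()]: a key/value
#' header terminated by `***EndOfHeader***;`, followed by one
#' semicolon-separated data line per 10-bp damage site. Header keys outside
#' the parsed set are preserved verbatim in `free_fields` (a message lists
#' them). Records appear in file order, so per-track groups are retrievable
#' by `track_id`.
#'
#' @param path Path to an SDD text file, or a connection.
#' @return A list with elements `header` (an [sdd_header()]) and `records`
#'   (a [damage_sites()] data frame, zero rows for a header-only file).
#' @examples
#' f <- tempfile(fileext = ".sdd")
#' rec <- damage_sites(track_id = 1, n_sb_strand1 = 1, n_sb_strand2 = 1)
#' write_sdd(sdd_header(particle = "proton"), rec, f)
#' sdd <- read_sdd(f)
#' nrow(sdd$records)
#' @export
read_sdd <- function(path) {
  lines <- readLines(path)
  sent <- which(trimws(lines) == .sdd_sentinel)
  if (length(sent) == 0L)
    stop("malformed SDD header: missing '", .sdd_sentinel, "' sentinel",
         call. = FALSE)
  sent <- sent[1]

  fields <- list(site_definition_bp = 10L, dose_unit = "Gy")
  free <- list()
  for (i in seq_len(sent - 1L)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    if (!grepl(",", line, fixed = TRUE) || !endsWith(line, ";"))
      stop(sprintf("malformed SDD header at line %d: '%s'", i, line),
           call. = FALSE)
    line <- sub(";$", "", line)
    key <- trimws(sub(",.*$", "", line))
    val <- trimws(sub("^[^,]*,", "", line))
    slot <- .sdd_known_keys[key]
    if (is.na(slot) || slot == "sdd_version") {
      if (!is.na(slot)) next  # version line: accepted, not stored
      free[[key]] <- val
    } else if (slot == "dose_or_fluence") {
      parts <- trimws(strsplit(val, ",")[[1]])
      fields$dose_unit <- if (parts[1] %in% c("2", "/um2")) "/um2" else "Gy"
      fields$dose_or_fluence <- suppressWarnings(as.numeric(parts[length(parts)]))
    } else if (slot %in% c("energy_MeV", "site_definition_bp")) {
      if (val == ".") {
        if (slot == "energy_MeV") fields[[slot]] <- NA_real_
        next
      }
      fields[[slot]] <- suppressWarnings(as.numeric(val))
      if (is.na(fields[[slot]]))
        stop(sprintf("malformed SDD header at line %d: non-numeric '%s'", i, key),
             call. = FALSE)
    } else {
      fields[[slot]] <- val
    }
  }
  if (length(free))
    message("SDD header keys passed through unparsed: ",
            paste(names(free), collapse = ", "))
  header <- sdd_header(
    simulator_name = fields$simulator_name %||% NA_character_,
    dose_or_fluence = fields$dose_or_fluence %||% NA_real_,
    dose_unit = fields$dose_unit,
    particle = fields$particle %||% NA_character_,
    energy_MeV = fields$energy_MeV %||% NA_real_,
    site_definition_bp = fields$site_definition_bp,
    free_fields = free
  )

  data_lines <- lines[seq.int(sent + 1L, length.out = length(lines) - sent)]
  data_lines <- data_lines[trimws(data_lines) != ""]
  if (length(data_lines) == 0L) {
    return(list(header = header, records = empty_damage_sites()))
  }
  records <- parse_sdd_data(data_lines, first_line_number = sent + 1L)
  list(header = header, records = records)
}

empty_damage_sites <- function() {
  damage_sites(track_id = integer(0))
}

parse_sdd_data <- function(data_lines, first_line_number) {
  parse_one <- function(line, lineno) {
    f <- trimws(strsplit(sub(";\\s*$", "", line), ";")[[1]])
    if (length(f) != 10L)
      stop(sprintf("record error at line %d: expected 10 fields, found %d",
                   lineno, length(f)), call. = FALSE)
    xyz <- suppressWarnings(as.numeric(trimws(strsplit(f[4], ",")[[1]])))
    if (length(xyz) != 3L || anyNA(xyz))
      stop(sprintf("record error at line %d: bad spatial position '%s'",
                   lineno, f[4]), call. = FALSE)
    int_or_na <- function(s) {
      if (s == ".") return(NA_integer_)
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v) || v != round(v) || v < 0)
        stop(sprintf("record error at line %d: '%s' is not a non-negative integer",
                     lineno, s), call. = FALSE)
      as.integer(v)
    }
    counts <- vapply(f[c(1:3, 5:7, 9:10)], int_or_na, integer(1))
    dsb_raw <- int_or_na(f[8])
    list(track_id = counts[1], chromosome_id = counts[2],
         genomic_position_bp = counts[3],
         x_um = xyz[1], y_um = xyz[2], z_um = xyz[3],
         n_sb_strand1 = counts[4], n_sb_strand2 = counts[5], n_bd = counts[6],
         has_dsb = if (is.na(dsb_raw)) NA else dsb_raw > 0L,
         cause_direct = counts[7], cause_indirect = counts[8])
  }
  rows <- mapply(parse_one, data_lines,
                 first_line_number + seq_along(data_lines) - 1L,
                 SIMPLIFY = FALSE)
  damage_sites(
    track_id = vapply(rows, `[[`, integer(1), "track_id"),
    chromosome_id = vapply(rows, `[[`, integer(1), "chromosome_id"),
    genomic_position_bp = vapply(rows, `[[`, integer(1), "genomic_position_bp"),
    x_um = vapply(rows, `[[`, numeric(1), "x_um"),
    y_um = vapply(rows, `[[`, numeric(1), "y_um"),
    z_um = vapply(rows, `[[`, numeric(1), "z_um"),
    n_sb_strand1 = vapply(rows, `[[`, integer(1), "n_sb_strand1"),
    n_sb_strand2 = vapply(rows, `[[`, integer(1), "n_sb_strand2"),
    n_bd = vapply(rows, `[[`, integer(1), "n_bd"),
    has_dsb = vapply(rows, function(r) as.logical(r$has_dsb), logical(1)),
    cause_direct = vapply(rows, `[[`, integer(1), "cause_direct"),
    cause_indirect = vapply(rows, `[[`, integer(1), "cause_indirect")
  )
}

#' Write a Standard DNA Damage (SDD) file
#'
#' Serializes a header and damage-site records in the canonical minimal
#' dialect understood by [read_sdd()]. Records are validated before any
#' output is written; the round trip `read_sdd(write_sdd(...))` preserves
#' header fields and all record columns, and re-writing a file read back
#' reproduces the data section byte for byte.
#'
#' @param header An [sdd_header()].
#' @param records A [damage_sites()] data frame (zero rows allowed).
#' @param path Output file path or connection.
#' @return `path`, invisibly.
#' @export
write_sdd <- function(header, records, path) {
  stopifnot(inherits(header, "sdd_header"))
  records <- validate_damage_sites(records)

  fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.9g", x))
  fmt_int <- function(x) ifelse(is.na(x), ".", sprintf("%d", x))
  hdr <- c(
    "SDD version, 1.0;",
    sprintf("Software, %s;", header$simulator_name),
    sprintf("Dose or fluence, %s, %s;",
            if (header$dose_unit == "Gy") "1" else "2",
            fmt_num(header$dose_or_fluence)),
    sprintf("Particle, %s;", header$particle),
    sprintf("Energy, %s;", fmt_num(header$energy_MeV)),
    sprintf("Damage definition, %d;", header$site_definition_bp),
    vapply(names(header$free_fields),
           function(k) sprintf("%s, %s;", k, header$free_fields[[k]]),
           character(1)),
    .sdd_sentinel
  )
  data <- character(0)
  if (nrow(records) > 0) {
    data <- sprintf(
      "%d; %d; %d; %s, %s, %s; %d; %d; %d; %d; %s; %s;",
      records$track_id, records$chromosome_id, records$genomic_position_bp,
      fmt_num(records$x_um), fmt_num(records$y_um), fmt_num(records$z_um),
      records$n_sb_strand1, records$n_sb_strand2, records$n_bd,
      as.integer(records$has_dsb),
      fmt_int(records$cause_direct), fmt_int(records$cause_indirect)
    )
  }
  writeLines(c(hdr, data), path)
  invisible(path)
}
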