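#' Construct a proteome group
#'
#' A proteome group is a named set of protein sequences, the unit of every
#' comparative analysis (e.g. younger lens, older lens, zonules).
#'
#' @param name Group name (non-empty string).
#' @param sequences Named character vector of amino-acid sequences
#'   (uppercase, canonical 20-letter alphabet); names are protein ids and
#'   must be unique and non-empty.
#' @return An object of class `proteome_group`: a list with elements
#'   `name` and `sequences`.
#' @export
proteome_group <- function(name, sequences) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(sequences) < 1L)
    stop("proteome group '", name, "' has no records")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence needs a non-empty protein id")
  if (anyDuplicated(ids))
    stop("duplicate protein ids in group '", name, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(sequences) < 1L))
    stop("zero-length sequence in group '", name, "'")
  bad <- grepl(sprintf("[^%s]", paste(AA_CANONICAL, collapse = "")), sequences)
  if (any(bad))
    stop("non-canonical residues in: ", paste(ids[bad], collapse = ", "))
  structure(list(name = name, sequences = sequences),
            class = "proteome_group")
}

#' @export
print.proteome_group <- function(x, ...) {
  cat("<proteome_group>", x$name, "-", length(x$sequences), "proteins,",
      sum(nchar(x$sequences)), "residues\n")
  invisible(x)
}

#' Construct a per-residue disorder track
#'
#' @param protein_id Protein identifier.
#' @param predictor Predictor name (e.g. `"vsl2b"`, `"MDP"`, `"baseline"`).
#' @param scores Numeric vector of per-residue disorder scores in \[0, 1\],
#'   one per residue from N- to C-terminus.
#' @return An object of class `disorder_track`.
#' @export
disorder_track <- function(protein_id, predictor, scores) {
  stopifnot(is.character(protein_id), length(protein_id) == 1L,
            is.character(predictor), length(predictor) == 1L)
  scores <- as.numeric(scores)
  if (length(scores) < 1L)
    stop("empty track for ", protein_id, "/", predictor)
  if (anyNA(scores) || any(scores < 0) || any(scores > 1))
    stop("scores outside [0,1] for ", protein_id, "/", predictor)
  structure(list(protein_id = protein_id, predictor = predictor,
                 scores = scores),
            class = "disorder_track")
}

#' Construct an expression table for one sample pool
#'
#' @param pool_id Pool identifier.
#' @param mean_age Mean donor age of the pool, in years (>= 0).
#' @param abundance Named non-negative numeric vector mapping protein id to
#'   expression level; at least one entry must be strictly positive.
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(pool_id, mean_age, abundance) {
  stopifnot(is.character(pool_id), length(pool_id) == 1L,
            is.numeric(mean_age), length(mean_age) == 1L, mean_age >= 0)
  if (length(abundance) == 0L)
    stop("no proteins in pool '", pool_id, "'")
  if (is.null(names(abundance)) || any(!nzchar(names(abundance))))
    stop("abundances must be named by protein id")
  if (anyNA(abundance) || any(abundance < 0))
    stop("negative or missing abundance in pool '", pool_id, "'")
  if (all(abundance == 0))
    stop("all abundances zero in pool '", pool_id, "'")
  structure(list(pool_id = pool_id, mean_age = as.numeric(mean_age),
                 abundance = abundance),
            class = "expression_table")
}

# Normalize raw sequences under an ambiguous-residue policy.
# B/Z/X/U/O are the ambiguity codes handled; any other non-canonical
# character is always an error.
AA_AMBIGUOUS_MAP <- c(B = "N", Z = "Q", U = "C", O = "K", X = "")

normalize_sequences <- function(seqs, policy, where = "fasta") {
  policy <- match.arg(policy, c("drop_ambiguous", "strict", "map_to_nearest"))
  seqs <- toupper(seqs)
  other <- grepl(sprintf("[^%s%s]", paste(AA_CANONICAL, collapse = ""),
                         paste(names(AA_AMBIGUOUS_MAP), collapse = "")), seqs)
  if (any(other))
    stop("unrecognized residue letters in ", where, ": ",
         paste(names(seqs)[other], collapse = ", "))
  amb_pat <- sprintf("[%s]", paste(names(AA_AMBIGUOUS_MAP), collapse = ""))
  has_amb <- grepl(amb_pat, seqs)
  if (!any(has_amb)) return(seqs)
  if (policy == "strict")
    stop("ambiguous residues (B/Z/X/U/O) in ", where, ": ",
         paste(names(seqs)[has_amb], collapse = ", "))
  if (policy == "drop_ambiguous") {
    warning(sum(has_amb), " sequence(s) contained ambiguous residues; ",
            "ambiguous letters dropped")
    seqs[has_amb] <- gsub(amb_pat, "", seqs[has_amb])
  } else {
    warning(sum(has_amb), " sequence(s) contained ambiguous residues; ",
            "mapped B>N Z>Q U>C O>K, X dropped")
    for (a in names(AA_AMBIGUOUS_MAP))
      seqs <- gsub(a, AA_AMBIGUOUS_MAP[[a]], seqs, fixed = TRUE)
  }
  seqs
}

#' Read a proteome group from a FASTA file
#'
#' Wrapped lines are joined and sequences are uppercased. The protein id is
#' the first whitespace-delimited token of the header. Ambiguous residue
#' letters (B, Z, X, U, O) are handled per `policy`; any other
#' non-canonical letter is an error under every policy.
#'
#' @param path Path to a FASTA file.
#' @param name Group name; defaults to the file name without extension.
#' @param policy One of `"drop_ambiguous"` (remove ambiguous letters, warn;
#'   the default), `"strict"` (error), `"map_to_nearest"` (B→N, Z→Q, U→C,
#'   O→K, X dropped; warn).
#' @return A [proteome_group()].
#' @export
read_fasta <- function(path, name = NULL,
                       policy = c("drop_ambiguous", "strict",
                                  "map_to_nearest")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aas))
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- setNames(as.character(aas), ids)
  seqs <- normalize_sequences(seqs, policy, where = path)
  if (any(nchar(seqs) == 0L))
    stop("sequence(s) empty after ambiguity handling: ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  proteome_group(name, seqs)
}

#' Write a proteome group to a FASTA file
#'
#' @param group A [proteome_group()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(group, path) {
  stopifnot(inherits(group, "proteome_group"))
  aas <- Biostrings::AAStringSet(group$sequences)
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Read per-residue disorder score tracks from TSV
#'
#' Expects tab-separated columns `protein_id`, `predictor`,
#' `residue_index` (1-based), `score`; lines starting with `#` are ignored.
#' Rows are grouped by (protein, predictor), sorted by residue index, and
#' each track must cover indices 1..L with no gaps or duplicates.
#'
#' @param path Path to the track TSV.
#' @return A list of [disorder_track()] objects.
#' @export
read_score_tracks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "predictor", "residue_index", "score")
  if (!all(need %in% names(df)))
    stop("track file must have columns ", paste(need, collapse = ", "))
  if (!is.numeric(df$score))
    stop("non-numeric score values in ", path)
  if (anyNA(df$score) || any(df$score < 0) || any(df$score > 1))
    stop("scores outside [0,1] in ", path)
  key <- paste(df$protein_id, df$predictor, sep = "\r")
  tracks <- lapply(split(seq_len(nrow(df)), key), function(i) {
    sub <- df[i, ]
    sub <- sub[order(sub$residue_index), ]
    L <- nrow(sub)
    if (!identical(as.integer(sub$residue_index), seq_len(L)))
      stop("residue indices for ", sub$protein_id[1], "/", sub$predictor[1],
           " are not contiguous 1..", L)
    disorder_track(sub$protein_id[1], sub$predictor[1], sub$score)
  })
  unname(tracks)
}

#' Write disorder tracks to the track TSV dialect
#'
#' @param tracks A list of [disorder_track()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_tracks <- function(tracks, path) {
  df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(protein_id = tr$protein_id, predictor = tr$predictor,
               residue_index = seq_along(tr$scores), score = tr$scores)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression table for one pool
#'
#' The dialect is: leading metadata lines `#pool_id=<id>` and
#' `#mean_age=<years>`, then a tab-separated header `protein_id abundance`
#' and one row per protein.
#'
#' @param path Path to the expression TSV.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- grep(sprintf("^#%s=", key), meta, value = TRUE)
    if (length(hit) != 1L)
      stop("expression file must carry exactly one '#", key, "=' line")
    sub(sprintf("^#%s=", key), "", hit)
  }
  pool_id <- get_meta("pool_id")
  mean_age <- suppressWarnings(as.numeric(get_meta("mean_age")))
  if (is.na(mean_age)) stop("non-numeric #mean_age= header")
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) < 2L) stop("no proteins in pool '", pool_id, "'")
  df <- read.delim(text = body, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "abundance") %in% names(df)))
    stop("malformed header: need columns protein_id, abundance")
  if (!is.numeric(df$abundance)) stop("non-numeric abundance in ", path)
  expression_table(pool_id, mean_age,
                   setNames(df$abundance, df$protein_id))
}

#' Write an expression table in the pool TSV dialect
#'
#' @param table An [expression_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path) {
  stopifnot(inherits(table, "expression_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#pool_id=%s", table$pool_id),
               sprintf("#mean_age=%s", format(table$mean_age)),
               "protein_id\tabundance"), con)
  writeLines(sprintf("%s\t%s", names(table$abundance),
                     format(table$abundance, trim = TRUE, scientific = FALSE)),
             con)
  invisible(path)
}

#' Check a disorder track against its protein sequence
#'
#' Track length must equal sequence length; a mismatch is an error rather
#' than a truncation, since silent truncation would corrupt ADS and PPDR.
#'
#' @param track A [disorder_track()].
#' @param group A [proteome_group()] holding the corresponding protein.
#' @return `TRUE`, invisibly, if consistent.
#' @export
check_track_lengths <- function(track, group) {
  stopifnot(inherits(track, "disorder_track"),
            inherits(group, "proteome_group"))
  idx <- match(track$protein_id, names(group$sequences))
  if (is.na(idx))
    stop("protein ", track$protein_id, " not in group '", group$name, "'")
  seq <- group$sequences[[idx]]
  if (nchar(seq) != length(track$scores))
    stop("track length ", length(track$scores), " != sequence length ",
         nchar(seq), " for ", track$protein_id, "/", track$predictor)
  invisible(TRUE)
}
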