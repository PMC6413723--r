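#' Read promoter sequences from a FASTA file
#'
#' Parses a standard FASTA file of promoter sequences (nominally 1 kb upstream
#' of each transcription start site) into a promoter set. The token before the
#' first whitespace in each header is taken as the gene identifier; sequence
#' lines may be wrapped at any width and are uppercased on read.
#'
#' @param path Path to a FASTA file. Only the alphabet `A,C,G,T,N` (either
#'   case) is accepted.
#' @return A tibble of class `promoter_set` with columns `gene_id` and
#'   `sequence`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 first", "acgt", "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) abort("empty FASTA file")
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) abort("FASTA must start with a '>' header line")
  bad <- which(!is_header & grepl("[^ACGTNacgtn]", lines))
  if (length(bad) > 0L) {
    abort(sprintf(
      "invalid sequence character on line %d (only A,C,G,T,N allowed)", bad[1L]
    ))
  }
  rec <- cumsum(is_header)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[is_header]))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- vapply(
    split(lines[!is_header], rec[!is_header]),
    function(x) toupper(paste(x, collapse = "")),
    character(1)
  )
  if (length(seqs) != length(ids) || any(nchar(seqs) == 0L)) {
    abort("every FASTA record must have a non-empty sequence")
  }
  new_promoter_set(tibble::tibble(gene_id = ids, sequence = unname(seqs)))
}

new_promoter_set <- function(x) {
  stopifnot(all(c("gene_id", "sequence") %in% names(x)))
  if (anyDuplicated(x$gene_id)) abort("duplicate gene ids in promoter set")
  structure(x, class = c("promoter_set", class(tibble::as_tibble(x))))
}

#' Write a promoter set to FASTA
#'
#' @param x A `promoter_set` (or any tibble with `gene_id` and `sequence`).
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  out <- purrr::map2(x$gene_id, x$sequence, function(id, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  readr::write_lines(unlist(out), path)
  invisible(path)
}

#' Read a TRANSFAC-style PWM library
#'
#' Parses the common public TRANSFAC matrix dialect: blocks introduced by an
#' `ID` (or `NA`) line naming the factor, a `P0`/`PO` header giving the base
#' column order, numbered position rows with four non-negative counts (an
#' optional trailing consensus letter is ignored), and a terminating `//`.
#'
#' @param path Path to the matrix file.
#' @return A list of `pwm` objects. Each has `tf_name` and a 4 x L numeric
#'   `matrix` with rows `A,C,G,T` in that fixed order.
#' @export
read_pwm_library <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- trimws(readr::read_lines(path))
  lines <- lines[nzchar(lines)]
  breaks <- c(0L, which(lines == "//"))
  if (length(breaks) < 2L) abort("no '//'-terminated matrix block found")
  blocks <- purrr::map2(
    breaks[-length(breaks)] + 1L, breaks[-1L] - 1L,
    function(i, j) if (j >= i) lines[i:j] else character(0)
  )
  blocks <- purrr::keep(blocks, ~ length(.x) > 0)
  purrr::map(blocks, parse_transfac_block)
}

parse_transfac_block <- function(block) {
  id_line <- grep("^(ID|NA)\\s+", block, value = TRUE)
  name <- if (length(id_line) > 0L) {
    strsplit(id_line[1L], "\\s+")[[1L]][2L]
  } else {
    "unnamed"
  }
  head_i <- grep("^P[O0]\\b", block)
  if (length(head_i) == 0L) {
    abort(paste0("PWM block '", name, "': missing P0 column header"))
  }
  bases <- toupper(strsplit(block[head_i[1L]], "\\s+")[[1L]][-1L])
  if (!identical(sort(bases), c("A", "C", "G", "T"))) {
    abort(paste0("PWM block '", name, "': column header must name A, C, G, T"))
  }
  rows <- grep("^\\d+\\s", block, value = TRUE)
  if (length(rows) == 0L) abort(paste0("PWM block '", name, "': no position rows"))
  counts <- purrr::map(rows, function(r) {
    f <- strsplit(r, "\\s+")[[1L]][-1L]
    # drop a trailing consensus letter if present
    if (length(f) > 0L && grepl("^[A-Za-z]+$", f[length(f)])) f <- f[-length(f)]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) != 4L || anyNA(v)) {
      abort(paste0("PWM block '", name, "': position row must have 4 counts"))
    }
    if (any(v < 0)) abort(paste0("PWM block '", name, "': negative count"))
    v
  })
  m <- do.call(cbind, counts)
  rownames(m) <- bases
  m <- m[c("A", "C", "G", "T"), , drop = FALSE]
  new_pwm(name, m)
}

#' Construct a PWM object
#'
#' @param tf_name Transcription-factor name.
#' @param matrix 4 x L non-negative numeric matrix, rows `A,C,G,T` in that
#'   order (counts or frequencies).
#' @return An object of class `pwm`.
#' @export
new_pwm <- function(tf_name, matrix) {
  if (!is.matrix(matrix) || nrow(matrix) != 4L) {
    abort("PWM matrix must have 4 rows (A, C, G, T)")
  }
  if (ncol(matrix) < 4L) abort("PWM must have length >= 4")
  if (any(!is.finite(matrix)) || any(matrix < 0)) {
    abort("PWM entries must be finite and non-negative")
  }
  if (any(colSums(matrix) == 0)) abort("PWM has an all-zero column")
  rownames(matrix) <- c("A", "C", "G", "T")
  structure(list(tf_name = tf_name, matrix = matrix), class = "pwm")
}

#' @exportS3Method base::print
print.pwm <- function(x, ...) {
  cat("<pwm>", x$tf_name, "length", ncol(x$matrix), "\n")
  print(x$matrix)
  invisible(x)
}

#' Write a PWM library in TRANSFAC-style text
#'
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm_library <- function(pwms, path) {
  out <- purrr::map(pwms, function(p) {
    m <- p$matrix
    c(
      paste("ID", p$tf_name),
      paste("P0", "A", "C", "G", "T", sep = "\t"),
      vapply(seq_len(ncol(m)), function(i) {
        paste(c(sprintf("%02d", i), format(m[, i], trim = TRUE)), collapse = "\t")
      }, character(1)),
      "//"
    )
  })
  readr::write_lines(unlist(out), path)
  invisible(path)
}

#' Read gene-set annotations in GMT format
#'
#' One term per line: term id, description, then member gene ids, all
#' tab-separated.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `term_id`, `term_name` and list-column
#'   `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0L) {
    abort(sprintf("GMT line %d has fewer than 3 fields", short[1L]))
  }
  tibble::tibble(
    term_id = vapply(parts, `[`, character(1), 1L),
    term_name = vapply(parts, `[`, character(1), 2L),
    members = purrr::map(parts, ~ unique(.x[-(1:2)]))
  )
}

#' Write gene-set annotations in GMT format
#'
#' @param x Tibble with `term_id`, `term_name`, list-column `members`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  lines <- purrr::pmap_chr(
    list(x$term_id, x$term_name, x$members),
    function(id, nm, mem) paste(c(id, nm, mem), collapse = "\t")
  )
  readr::write_lines(lines, path)
  invisible(path)
}

# ---- typed TSV tables -------------------------------------------------------

table_schemas <- list(
  edges = c("node_a", "node_b", "combined_score"),
  ranked_profile = c("drug_id", "rank", "gene_id"),
  de_table = c("gene_id", "log2fc", "p_value"),
  ortholog_map = c("mouse_gene", "human_gene"),
  ct_values = c("sample_id", "condition", "gene_id", "ct")
)

#' Read a typed tab-separated table
#'
#' The canonical table dialect is TSV with a header row; comma-separated input
#' is rejected rather than guessed. The `expression` schema expects a
#' `gene_id` column plus one column per sample and a second header row of the
#' form `#condition<TAB>label...` mapping each sample to its condition.
#'
#' @param path Path to a TSV file.
#' @param schema One of `"expression"`, `"edges"`, `"ranked_profile"`,
#'   `"de_table"`, `"ortholog_map"`, `"ct_values"`.
#' @param score_scale For `edges` only: `"unit"` takes combined scores as
#'   given on \[0,1\]; `"string999"` divides raw STRING-export scores by 999.
#' @return The corresponding domain object: an `expression_matrix` for
#'   `"expression"`, otherwise a validated tibble.
#' @export
read_table <- function(path, schema, score_scale = c("unit", "string999")) {
  schema <- match.arg(schema, c("expression", names(table_schemas)))
  score_scale <- match.arg(score_scale)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (schema == "expression") return(read_expression_tsv(path))
  header <- strsplit(readr::read_lines(path, n_max = 1L), "\t", fixed = TRUE)[[1L]]
  required <- table_schemas[[schema]]
  missing <- setdiff(required, header)
  if (length(missing) > 0L) {
    abort(paste0(
      "missing required column(s) for schema '", schema, "': ",
      paste(missing, collapse = ", "),
      " (is the file tab-separated?)"
    ))
  }
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  numeric_cols <- switch(schema,
    edges = "combined_score",
    ranked_profile = "rank",
    de_table = c("log2fc", "p_value"),
    ortholog_map = character(0),
    ct_values = "ct"
  )
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      abort(sprintf("non-numeric or non-finite value in column '%s', row %d",
                    col, bad[1L]))
    }
    x[[col]] <- v
  }
  switch(schema,
    edges = {
      if (score_scale == "string999") x$combined_score <- x$combined_score / 999
      new_interaction_edges(x)
    },
    ranked_profile = validate_ranked_profiles(x),
    de_table = {
      if (any(x$p_value < 0 | x$p_value > 1)) abort("p_value outside [0,1]")
      if (anyDuplicated(x$gene_id)) {
        abort(paste0("duplicate gene in de_table: ",
                     x$gene_id[duplicated(x$gene_id)][1L]))
      }
      x
    },
    ortholog_map = x,
    ct_values = {
      if (any(x$ct <= 0 | x$ct >= 45)) abort("Ct values must lie in (0, 45)")
      x
    }
  )
}

read_expression_tsv <- function(path) {
  first2 <- readr::read_lines(path, n_max = 2L)
  header <- strsplit(first2[1L], "\t", fixed = TRUE)[[1L]]
  if (header[1L] != "gene_id") {
    abort("expression table must have 'gene_id' as its first column (tab-separated)")
  }
  if (length(first2) < 2L || !startsWith(first2[2L], "#condition")) {
    abort("expression table needs a second header row '#condition<TAB>...' mapping samples to conditions")
  }
  cond <- strsplit(first2[2L], "\t", fixed = TRUE)[[1L]][-1L]
  samples <- header[-1L]
  if (length(cond) != length(samples)) {
    abort("condition row length does not match the number of sample columns")
  }
  x <- readr::read_tsv(path, skip = 2L, col_names = header,
                       col_types = readr::cols(
                         gene_id = readr::col_character(),
                         .default = readr::col_double()
                       ),
                       progress = FALSE)
  new_expression_matrix(x, stats::setNames(cond, samples))
}

#' Construct an expression matrix
#'
#' A genes-by-samples table of non-negative abundances (FPKM-like) for a
#' two-condition design, stored as a wide tibble (`gene_id` plus one numeric
#' column per sample) carrying the sample-to-condition map as an attribute.
#'
#' @param x Tibble with `gene_id` plus one numeric column per sample.
#' @param conditions Named character vector: sample id -> condition label.
#'   Exactly two distinct labels; each condition needs >= 2 samples.
#' @return A tibble of class `expression_matrix`.
#' @export
new_expression_matrix <- function(x, conditions) {
  x <- tibble::as_tibble(x)
  samples <- setdiff(names(x), "gene_id")
  if (anyDuplicated(x$gene_id)) abort("duplicate gene ids in expression matrix")
  if (anyDuplicated(samples)) abort("duplicate sample ids in expression matrix")
  if (!setequal(names(conditions), samples)) {
    abort("every sample column needs a condition label (and no extras)")
  }
  conditions <- conditions[samples]
  if (length(unique(conditions)) != 2L) {
    abort("expression matrix must have exactly two condition labels")
  }
  if (any(table(conditions) < 2L)) abort("each condition needs >= 2 samples")
  vals <- as.matrix(x[samples])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("expression values must be finite and >= 0")
  }
  structure(x, conditions = conditions,
            class = unique(c("expression_matrix", class(x))))
}

#' Extract the sample-to-condition map of an expression matrix
#' @param x An `expression_matrix`.
#' @return Named character vector, sample id -> condition label.
#' @export
conditions_of <- function(x) attr(x, "conditions")

#' Write a typed tab-separated table
#'
#' Inverse of [read_table()]: writes the two-header-row dialect for
#' `expression` and plain TSV for the other schemas, at full precision.
#'
#' @param x Domain object (e.g. `expression_matrix`, edges tibble).
#' @param path Output path.
#' @param schema Same choices as [read_table()].
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, schema) {
  schema <- match.arg(schema, c("expression", names(table_schemas)))
  if (schema == "expression") {
    cond <- conditions_of(x)
    samples <- setdiff(names(x), "gene_id")
    header <- paste(c("gene_id", samples), collapse = "\t")
    cond_row <- paste(c("#condition", unname(cond[samples])), collapse = "\t")
    body <- do.call(paste, c(list(x$gene_id),
                             lapply(x[samples], format_full), list(sep = "\t")))
    readr::write_lines(c(header, cond_row, body), path)
  } else {
    out <- tibble::as_tibble(x)
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], format_full)
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

format_full <- function(v) {
  if (is.numeric(v) && !is.integer(v)) format(v, digits = 17, trim = TRUE, scientific = FALSE)
  else v
}

new_interaction_edges <- function(x) {
  x <- tibble::as_tibble(x)[c("node_a", "node_b", "combined_score")]
  if (any(x$combined_score < 0 | x$combined_score > 1)) {
    abort("combined_score must lie in [0,1] (use score_scale = 'string999' for raw STRING exports)")
  }
  if (any(x$node_a == x$node_b)) abort("self-loop edge found")
  key <- paste(pmin(x$node_a, x$node_b), pmax(x$node_a, x$node_b))
  if (anyDuplicated(key)) abort("duplicate (unordered) edge found")
  structure(x, class = unique(c("interaction_edges", class(x))))
}

validate_ranked_profiles <- function(x) {
  x <- tibble::as_tibble(x)
  x$rank <- as.numeric(x$rank)
  bad <- x |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::summarise(
      dup_gene = {d <- .data$gene_id[duplicated(.data$gene_id)]; if (length(d)) d[1] else NA_character_},
      ok_ranks = identical(sort(.data$rank), as.numeric(seq_along(.data$rank)))
    )
  if (any(!is.na(bad$dup_gene))) {
    off <- bad[!is.na(bad$dup_gene), ]
    abort(paste0("duplicate gene '", off$dup_gene[1L], "' in profile of drug '",
                 off$drug_id[1L], "'"))
  }
  if (any(!bad$ok_ranks)) {
    abort(paste0("ranks of drug '", bad$drug_id[!bad$ok_ranks][1L],
                 "' are not a permutation of 1..n"))
  }
  structure(x, class = unique(c("ranked_profiles", class(x))))
}
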