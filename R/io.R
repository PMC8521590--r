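## ---------------------------------------------------------------------------
## Readers and writers.  Internal coordinates are 0-based half-open
## everywhere; GFF3 (1-based closed) is converted at the boundary.
## ---------------------------------------------------------------------------

#' Read gene positions from GFF3 or BED-like TSV
#'
#' Returns a table of gene positions with 0-based half-open coordinates.
#' GFF3 input (1-based closed, parsed with \pkg{rtracklayer}) is converted;
#' BED-like TSV input is expected to carry columns
#' `chromosome, start, end, gene_id, genome, strand` (header optional) and is
#' already 0-based half-open.
#'
#' @param path input file
#' @param format `"bed"` or `"gff3"`
#' @param genome genome name attached to every record (required for GFF3;
#'   overrides the file's `genome` column for BED when given)
#' @param feature GFF3 feature type to keep (default `"gene"`)
#' @return data.frame with columns `gene_id, genome, chromosome, start, end,
#'   strand`
#' @export
read_gene_positions <- function(path, format = c("bed", "gff3"),
                                genome = NULL, feature = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "gff3") {
    if (is.null(genome)) stop("'genome' must be given for GFF3 input")
    gr <- rtracklayer::import(path, format = "gff3")
    if (length(gr) == 0) {
      warning("empty gene position file: ", path)
      return(empty_gene_positions())
    }
    if (!is.null(feature) && "type" %in% names(S4Vectors::mcols(gr))) {
      keep <- as.character(gr$type) == feature
      if (any(keep)) gr <- gr[keep]
    }
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
    if (anyNA(ids)) stop("GFF3 records without ID/Name attribute")
    df <- data.frame(
      gene_id = ids, genome = genome,
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # 1-based closed -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  } else {
    first <- readLines(path, n = 1L)
    if (!length(first)) {
      warning("empty gene position file: ", path)
      return(empty_gene_positions())
    }
    has_header <- grepl("chromosome|gene_id", first)
    df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
    if (!has_header) {
      if (ncol(df) < 6) stop("BED-like TSV needs 6 columns ",
                             "(chromosome, start, end, gene_id, genome, strand)")
      names(df)[1:6] <- c("chromosome", "start", "end", "gene_id", "genome", "strand")
    }
    df <- df[, c("gene_id", "genome", "chromosome", "start", "end", "strand")]
    if (!is.null(genome)) df$genome <- genome
  }
  validate_gene_positions(df)
  message(nrow(df), " gene positions read from ", path)
  df
}

empty_gene_positions <- function() {
  data.frame(gene_id = character(), genome = character(),
             chromosome = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

validate_gene_positions <- function(df) {
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad)) stop("invalid coordinates (negative or inverted) at row(s) ",
                        paste(head(bad, 5), collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every gene")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ids: ",
         paste(head(unique(df$gene_id[duplicated(df$gene_id)]), 5), collapse = ", "))
  invisible(df)
}

#' Read ortholog/homolog pairs from a BlastP-like TSV
#'
#' Accepts either a 4-column table `gene_a, gene_b, identity, bitscore`
#' (header optional) or 12-column BLAST outfmt-6 (identity in column 3,
#' bitscore in column 12).  Unordered duplicate pairs are collapsed keeping
#' the maximum bitscore; self hits are dropped with a warning.
#'
#' @param path input TSV
#' @return data.frame with columns `gene_a, gene_b, identity, bitscore`
#' @export
read_ortholog_pairs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("gene_a|bitscore", first)
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) >= 12) {
    df <- df[, c(1, 2, 3, 12)]
  } else if (ncol(df) >= 4) {
    df <- df[, 1:4]
  } else stop("ortholog table needs >= 4 tab-separated columns")
  names(df) <- c("gene_a", "gene_b", "identity", "bitscore")
  if (!is.numeric(df$bitscore) || !is.numeric(df$identity))
    stop("non-numeric identity/bitscore column in ", path)
  if (any(df$bitscore < 0)) stop("negative bitscore")
  if (any(df$identity < 0 | df$identity > 100)) stop("identity outside [0, 100]")
  dedup_ortholog_pairs(df, path)
}

dedup_ortholog_pairs <- function(df, path = "<table>") {
  self <- df$gene_a == df$gene_b
  if (any(self)) {
    warning(sum(self), " self hit(s) dropped from ", path)
    df <- df[!self, , drop = FALSE]
  }
  a <- pmin(df$gene_a, df$gene_b); b <- pmax(df$gene_a, df$gene_b)
  key <- paste(a, b, sep = "\r")
  df$gene_a <- a; df$gene_b <- b
  o <- order(key, -df$bitscore, method = "radix")
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(key[o]), , drop = FALSE]
  rownames(df) <- NULL
  message(nrow(df), " unique ortholog pairs")
  df
}

## ---------------------------------------------------------------------------
## GRIMM-style genome files
## ---------------------------------------------------------------------------

#' Read a GRIMM-style genome file
#'
#' Format: a `>name` header, one chromosome per line, signed `marker.copy`
#' tokens separated by whitespace, each line terminated by `$`.
#'
#' @param path input file
#' @return a list of [genome()] objects (one per `>` record)
#' @export
read_grimm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  genomes <- list()
  cur_name <- NULL; cur_chroms <- list()
  flush <- function() {
    if (!is.null(cur_name)) genomes[[length(genomes) + 1L]] <<-
        genome(cur_chroms, name = cur_name)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (startsWith(ln, ">")) {
      flush()
      cur_name <- trimws(substring(ln, 2L)); cur_chroms <- list()
    } else {
      if (is.null(cur_name)) stop("line ", i, ": chromosome before any '>' header")
      toks <- strsplit(ln, "[[:space:]]+")[[1]]
      if (tail(toks, 1) != "$") stop("line ", i, ": missing '$' terminator")
      toks <- toks[-length(toks)]
      toks <- ifelse(grepl("^[+-]", toks), toks, paste0("+", toks))
      bad <- toks[!grepl(TOKEN_RE, toks)]
      if (length(bad)) stop("line ", i, ": malformed token(s): ",
                            paste(head(bad, 3), collapse = " "))
      if (length(toks)) cur_chroms[[length(cur_chroms) + 1L]] <- toks
    }
  }
  flush()
  genomes
}

#' Write genomes to a GRIMM-style file
#'
#' @param genomes a [genome()] or list of them
#' @param path output file
#' @return `path`, invisibly
#' @export
write_grimm <- function(genomes, path) {
  if (inherits(genomes, "scj_genome")) genomes <- list(genomes)
  con <- file(path, "w"); on.exit(close(con))
  for (g in genomes) {
    writeLines(paste0(">", g$name), con)
    for (ch in g$chromosomes) writeLines(paste(c(ch, "$"), collapse = " "), con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Ks tables and expression matrices
## ---------------------------------------------------------------------------

#' Read a Ks table
#'
#' TSV with header columns `gene_a, gene_b, ks` and optionally `pair_class`.
#' Missing or negative Ks values are rejected.
#'
#' @param path input TSV
#' @return data.frame
#' @export
read_ks_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "ks")
  if (!all(need %in% names(df)))
    stop("Ks table must have columns: ", paste(need, collapse = ", "))
  if (anyNA(df$ks)) stop("NA Ks values are not allowed")
  if (!is.numeric(df$ks) || any(df$ks < 0)) stop("Ks must be numeric and >= 0")
  if (!"pair_class" %in% names(df)) df$pair_class <- NA_character_
  df
}

#' Write a Ks table
#' @param df data.frame with `gene_a, gene_b, ks` (and optionals)
#' @param path output TSV
#' @export
write_ks_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TPM expression matrix
#'
#' TSV with a header of tissue names and gene ids in the first column.
#' Values must be non-negative; `NA` cells are rejected unless
#' `na_as_zero = TRUE`.
#'
#' @param path input TSV
#' @param na_as_zero replace `NA` cells by 0 instead of failing
#' @return numeric matrix (genes x tissues)
#' @export
read_expression_matrix <- function(path, na_as_zero = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
                 error = function(e) stop("malformed expression matrix: ",
                                          conditionMessage(e)))
  if (ncol(df) < 2) stop("expression matrix needs gene ids plus >= 1 tissue")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (anyNA(m)) {
    if (na_as_zero) m[is.na(m)] <- 0 else stop("NA cells in expression matrix")
  }
  if (any(m < 0)) stop("negative TPM values")
  m
}

#' Write a TPM expression matrix
#' @param m numeric matrix with gene-id rownames
#' @param path output TSV
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Result writers
## ---------------------------------------------------------------------------

#' Write pipeline outputs to a directory
#'
#' Ancestral genomes go to GRIMM files plus a TSV mapping each reconstructed
#' chromosome (CAR) to its member blocks; synteny blocks, the event log and
#' summary statistics each go to a TSV.
#'
#' @param dir output directory (created if needed)
#' @param ancestors named list of [genome()] objects (may be `NULL`)
#' @param blocks a `synteny_blocks` object (may be `NULL`)
#' @param events data.frame of rearrangement events (may be `NULL`)
#' @param stats data.frame of summary statistics (may be `NULL`)
#' @return `dir`, invisibly
#' @export
write_outputs <- function(dir, ancestors = NULL, blocks = NULL,
                          events = NULL, stats = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  if (!is.null(ancestors)) {
    write_grimm(ancestors, file.path(dir, "ancestors.grimm"))
    car <- do.call(rbind, lapply(ancestors, function(g) {
      do.call(rbind, lapply(seq_along(g$chromosomes), function(i) {
        data.frame(ancestor = g$name, car = paste0("CAR", i),
                   member = token_key(g$chromosomes[[i]]),
                   stringsAsFactors = FALSE)
      }))
    }))
    write.table(car, file.path(dir, "cars.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(blocks)) {
    write.table(block_copy_table(blocks), file.path(dir, "blocks.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(events)) {
    write.table(events, file.path(dir, "events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(stats)) {
    write.table(stats, file.path(dir, "stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
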