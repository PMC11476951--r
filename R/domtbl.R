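# HMMER3 per-domain table ("domtblout") I/O and profile-name mapping.
#
# hmmsearch is run with the Pfam profiles as queries against a proteome, so
# in the table the *target* is the protein isoform and the *query* is the
# domain profile.  The standard layout has 22 fixed whitespace-separated
# columns plus a free-text description.

# canonical profile labels used throughout the package
ZFP_PROFILES <- c("ZF_C2H2", "BTB", "HOMEO", "KRAB", "PHD", "SCAN", "SET")
ZFP_EFFECTORS <- setdiff(ZFP_PROFILES, "ZF_C2H2")

# Pfam accessions / common profile names -> canonical label
.profile_map <- c(
  "PF00096" = "ZF_C2H2", "zf-C2H2" = "ZF_C2H2",
  "PF00651" = "BTB",     "BTB" = "BTB",
  "PF00046" = "HOMEO",   "Homeodomain" = "HOMEO", "Homeobox" = "HOMEO",
  "PF01352" = "KRAB",    "KRAB" = "KRAB",
  "PF00628" = "PHD",     "PHD" = "PHD",
  "PF02023" = "SCAN",    "SCAN" = "SCAN",
  "PF00856" = "SET",     "SET" = "SET"
)

# reverse map used when writing synthetic tables
.profile_accession <- c(
  ZF_C2H2 = "PF00096.30", BTB = "PF00651.34", HOMEO = "PF00046.32",
  KRAB = "PF01352.30", PHD = "PF00628.32", SCAN = "PF02023.17",
  SET = "PF00856.31"
)
.profile_pfam_name <- c(
  ZF_C2H2 = "zf-C2H2", BTB = "BTB", HOMEO = "Homeodomain",
  KRAB = "KRAB", PHD = "PHD", SCAN = "SCAN", SET = "SET"
)

map_profile <- function(query_name, query_acc) {
  acc <- sub("\\..*$", "", query_acc)   # strip Pfam version suffix
  out <- unname(.profile_map[acc])
  out[is.na(out)] <- unname(.profile_map[query_name[is.na(out)]])
  out[is.na(out)] <- query_name[is.na(out)]   # unrecognized: keep raw name
  out
}

#' Parse HMMER3 per-domain tabular output
#'
#' Reads a `hmmsearch --domtblout` file and returns one row per domain hit
#' passing the independent E-value threshold.  The envelope coordinates
#' (`env from`/`env to`) are used as the domain location; input order is
#' preserved.
#'
#' @param path path to a domtblout file.
#' @param evalue_max maximum independent E-value (i-Evalue) for a per-domain
#'   row to be retained.  Default 0.05, the inclusion threshold used when
#'   scanning with `-E 0.05 -incE 0.05`.
#' @return a data.frame of domain hits with columns `isoform_id`, `profile`
#'   (canonical label, e.g. `"KRAB"`, `"ZF_C2H2"`), `env_start`, `env_end`
#'   (1-based inclusive residue coordinates), `i_evalue`, `score` and
#'   `target_len` (the isoform length reported by the scan).
#' @export
parse_domtblout <- function(path, evalue_max = 0.05) {
  if (!file.exists(path)) stop_arg("domtblout file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(
      isoform_id = character(), profile = character(),
      env_start = integer(), env_end = integer(),
      i_evalue = numeric(), score = numeric(), target_len = integer(),
      stringsAsFactors = FALSE
    ))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 23)
  if (length(bad)) {
    stop_arg(
      "malformed domtblout record at line ", idx[bad[1]],
      ": expected >= 23 whitespace-separated fields, found ", nf[bad[1]]
    )
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:22]))
  hits <- data.frame(
    isoform_id = m[, 1],
    profile    = map_profile(m[, 4], m[, 5]),
    env_start  = as.integer(m[, 20]),
    env_end    = as.integer(m[, 21]),
    i_evalue   = as.numeric(m[, 13]),
    score      = as.numeric(m[, 14]),
    target_len = as.integer(m[, 3]),
    stringsAsFactors = FALSE
  )
  if (anyNA(hits$i_evalue) || anyNA(hits$env_start) || anyNA(hits$env_end)) {
    first <- which(is.na(hits$i_evalue) | is.na(hits$env_start) | is.na(hits$env_end))[1]
    stop_arg("malformed domtblout record at line ", idx[first],
             ": non-numeric coordinate or E-value field")
  }
  hits <- hits[hits$i_evalue <= evalue_max, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write domain hits as a HMMER3-style per-domain table
#'
#' Inverse of [parse_domtblout()] for synthetic data: emits a syntactically
#' valid domtblout that round-trips through the parser.
#'
#' @param hits data.frame with columns `isoform_id`, `profile`, `env_start`,
#'   `env_end`, `i_evalue`, `score` and optionally `target_len`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  assert_df_cols(hits, c("isoform_id", "profile", "env_start", "env_end",
                         "i_evalue", "score"), "hits")
  tlen <- hits$target_len %||% NULL
  if (is.null(tlen)) tlen <- rep(999L, nrow(hits))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  ), con)
  qn <- .profile_pfam_name[hits$profile]
  qa <- .profile_accession[hits$profile]
  qn[is.na(qn)] <- hits$profile[is.na(qn)]
  qa[is.na(qa)] <- "-"
  qlen <- c(ZF_C2H2 = 23L, BTB = 111L, HOMEO = 57L, KRAB = 42L,
            PHD = 53L, SCAN = 84L, SET = 154L)[hits$profile]
  qlen[is.na(qlen)] <- 50L
  for (i in seq_len(nrow(hits))) {
    writeLines(sprintf(
      "%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.3g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f -",
      hits$isoform_id[i], "-", tlen[i], qn[i], qa[i], qlen[i],
      hits$i_evalue[i], hits$score[i] + 1, 0.1, 1L, 1L,
      hits$i_evalue[i] / 2, hits$i_evalue[i], hits$score[i], 0.1,
      1L, qlen[i], hits$env_start[i], hits$env_end[i],
      hits$env_start[i], hits$env_end[i], 0.95
    ), con)
  }
  writeLines("#", con)
  invisible(path)
}
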