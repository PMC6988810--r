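#' Default trophic assignment rules
#'
#' Group-level conventions for protist trophic modes: only diatoms
#' (Bacillariophyta) and Mamiellophyceae are treated as strict
#' autotrophs; other chloroplast-bearing groups are mixotrophs;
#' Labyrinthulea and Oomycota (parasites/commensalists/saprotrophs)
#' are lumped with the parasites, as are Syndiniales; ciliates and the
#' heterotrophic flagellate groups are heterotrophs.  Shipped as an
#' editable TSV (`taxon, rank, category`) so species- or genus-level
#' literature assignments can be layered on top; more specific ranks
#' take precedence.
#'
#' @return data.frame of class `trophic_rules`.
#' @export
default_trophic_rules <- function() {
  path <- system.file("extdata", "trophic_rules.tsv",
                      package = "protistnet", mustWork = TRUE)
  read_trophic_rules(path)
}

#' Read trophic rules from a TSV file
#'
#' @param path TSV with columns `taxon, rank, category`; `rank` one of
#'   species, genus, family, group; `category` one of autotroph,
#'   heterotroph, mixotroph, parasite, NA.
#' @return validated data.frame of class `trophic_rules`.
#' @export
read_trophic_rules <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          na.strings = character())
  trophic_rules(df)
}

#' Validate a trophic rule table
#'
#' Conflicting rules (same taxon and rank, different category) fail
#' loudly; rule order never matters because precedence is by rank
#' specificity alone.
#'
#' @param df data.frame with `taxon`, `rank`, `category`.
#' @return the validated rules.
#' @export
trophic_rules <- function(df) {
  need <- c("taxon", "rank", "category")
  if (!all(need %in% names(df)))
    stop("trophic rules need columns taxon, rank, category", call. = FALSE)
  ranks <- c("species", "genus", "family", "group")
  cats <- c("autotroph", "heterotroph", "mixotroph", "parasite", "NA")
  if (!all(df$rank %in% ranks))
    stop("unknown rank(s): ",
         paste(setdiff(df$rank, ranks), collapse = ", "), call. = FALSE)
  if (!all(df$category %in% cats))
    stop("unknown categor(ies): ",
         paste(setdiff(df$category, cats), collapse = ", "), call. = FALSE)
  key <- paste(df$taxon, df$rank, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    conf <- vapply(split(df$category, key), function(v)
      length(unique(v)) > 1L, logical(1))
    if (any(conf))
      stop("conflicting trophic rules at equal rank for: ",
           paste(sub("\r.*", "", names(conf)[conf]), collapse = ", "),
           call. = FALSE)
    df <- df[!duplicated(key), , drop = FALSE]
  }
  class(df) <- c("trophic_rules", "data.frame")
  df
}

# PR2-style 8-rank lineage positions
RANK_POS <- c(species = 8L, genus = 7L, family = 6L)

#' Assign trophic categories to OTUs
#'
#' The most specific matching rule wins (species > genus > family >
#' group).  Species/genus/family rules match the corresponding lineage
#' rank; group rules match the taxonomy table's high-level group label
#' or any lineage entry.  OTUs with no matching rule, or with an empty
#' lineage, get `"NA"` (unassignable trophic mode).
#'
#' @param taxa a `taxonomy_table`.
#' @param rules a `trophic_rules` (default [default_trophic_rules()]).
#' @return named character vector otu_id -> category.
#' @export
assign_trophic <- function(taxa, rules = default_trophic_rules()) {
  rules <- trophic_rules(as.data.frame(rules))
  rule_map <- function(rk) {
    sel <- rules$rank == rk
    stats::setNames(rules$category[sel], rules$taxon[sel])
  }
  maps <- lapply(c("species", "genus", "family"), rule_map)
  names(maps) <- c("species", "genus", "family")
  gmap <- rule_map("group")
  n_empty <- 0L
  out <- vapply(seq_len(nrow(taxa)), function(i) {
    lin <- taxa$lineage[[i]]
    if (length(lin) == 0L || all(lin == "unknown")) {
      n_empty <<- n_empty + 1L
      return("NA")
    }
    for (rk in c("species", "genus", "family")) {
      pos <- RANK_POS[[rk]]
      if (length(lin) >= pos && lin[pos] %in% names(maps[[rk]]))
        return(unname(maps[[rk]][lin[pos]]))
    }
    grp <- taxa$group[i]
    if (grp %in% names(gmap)) return(unname(gmap[grp]))
    hit <- lin[lin %in% names(gmap)]
    if (length(hit)) return(unname(gmap[hit[1L]]))
    "NA"
  }, character(1))
  if (n_empty > 0L)
    warning(sprintf("%d OTU(s) with empty lineage assigned NA", n_empty),
            call. = FALSE)
  stats::setNames(out, taxa$otu_id)
}

#' Trophic composition per habitat and date
#'
#' Relative read abundance of each trophic category (NA included)
#' within every `(habitat, date)` sample group; fractions sum to 1 per
#' group.
#'
#' @param table an [otu_table].
#' @param metadata a [sample_metadata].
#' @param categories named vector otu_id -> category covering all OTUs
#'   of the table.
#' @return data.frame with `habitat`, `date`, `category`, `fraction`.
#' @export
trophic_composition <- function(table, metadata, categories) {
  metadata <- sample_metadata(as.data.frame(metadata), table = table)
  miss <- setdiff(rownames(table), names(categories))
  if (length(miss))
    stop("OTUs without a trophic category: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  md <- metadata[match(colnames(table), metadata$sample_id), ]
  grp <- paste(md$habitat, md$date, sep = "\r")
  cat_f <- factor(categories[rownames(table)],
                  levels = c("autotroph", "heterotroph", "mixotroph",
                             "parasite", "NA"))
  rows <- list()
  for (g in unique(grp)) {
    sub <- table[, grp == g, drop = FALSE]
    tot <- sum(sub)
    if (tot == 0)
      stop("sample group with zero reads: ",
           sub("\r", " / ", g), call. = FALSE)
    reads <- tapply(rowSums(sub), cat_f, sum, default = 0)
    rows[[g]] <- data.frame(
      habitat = sub("\r.*", "", g), date = sub(".*\r", "", g),
      category = names(reads), fraction = as.numeric(reads) / tot,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
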