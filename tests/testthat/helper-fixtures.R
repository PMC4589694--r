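# shared fixture builders (everything is generated in code at test time)

tiny_panel <- function(seed = 101)
  amplimine::synthetic_methods_panel(n_event = 2, n_construct = 1,
                                     n_element = 1, n_taxon = 1, seed = seed)

write_methods_tsv <- function(methods, path = tempfile(fileext = ".tsv")) {
  tab <- methods
  tab$probe[is.na(tab$probe)] <- ""
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

one_method <- function(fw, rv, probe = NA_character_, id = "M1",
                       specificity = "event") {
  data.frame(method_id = id, specificity = specificity, target_name = "t",
             fw_primer = fw, rv_primer = rv, probe = probe,
             stringsAsFactors = FALSE)
}

# record with a planted block at a known offset inside fixed flanks
planted_record <- function(left, block, right, id = "rec1", label = "ds") {
  data.frame(record_id = id, description = "",
             sequence = paste0(left, block, right), dataset_label = label,
             stringsAsFactors = FALSE)
}
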