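{
  "de_up_ids": ["hsa-miR-s0107", "hsa-miR-s0699", "hsa-miR-s0329", "hsa-miR-s0667", "hsa-miR-s0033", "hsa-miR-s0551", "hsa-miR-s0745", "hsa-miR-s0030", "hsa-miR-s0064", "hsa-miR-s0150"],
  "de_down_ids": ["hsa-miR-s0129", "hsa-miR-s0574", "hsa-miR-s0286", "hsa-miR-s0336", "hsa-miR-s0750", "hsa-miR-s0270", "hsa-miR-s0095", "hsa-miR-s0338", "hsa-miR-s0302", "hsa-miR-s0716", "hsa-miR-s0612", "hsa-miR-s0284", "hsa-miR-s0243", "hsa-miR-s0035", "hsa-miR-s0646", "hsa-miR-s0439", "hsa-miR-s0119", "hsa-miR-s0088", "hsa-miR-s0219", "hsa-miR-s0110", "hsa-miR-s0273"],
  "de_vitd_up_ids": ["hsa-miR-s0107", "hsa-miR-s0699", "hsa-miR-s0329", "hsa-miR-s0667", "hsa-miR-s0033", "hsa-miR-s0551", "hsa-miR-s0745", "hsa-miR-s0030", "hsa-miR-s0064", "hsa-miR-s0272", "hsa-miR-s0211", "hsa-miR-s0340", "hsa-miR-s0611", "hsa-miR-s0586"],
  "de_vitd_down_ids": ["hsa-miR-s0129", "hsa-miR-s0574", "hsa-miR-s0286", "hsa-miR-s0336", "hsa-miR-s0750", "hsa-miR-s0270", "hsa-miR-s0095", "hsa-miR-s0567", "hsa-miR-s0570", "hsa-miR-s0713", "hsa-miR-s0436", "hsa-miR-s0203"],
  "shared_up_ids": ["hsa-miR-s0107", "hsa-miR-s0699", "hsa-miR-s0329", "hsa-miR-s0667", "hsa-miR-s0033", "hsa-miR-s0551", "hsa-miR-s0745", "hsa-miR-s0030", "hsa-miR-s0064"],
  "shared_down_ids": ["hsa-miR-s0129", "hsa-miR-s0574", "hsa-miR-s0286", "hsa-miR-s0336", "hsa-miR-s0750", "hsa-miR-s0270", "hsa-miR-s0095"],
  "hemolysed_ids": ["S041", "S077", "S146"],
  "planted_module_genes": ["G0007", "G0013", "G0017", "G0032", "G0052", "G0069", "G0080", "G0085", "G0096", "G0103", "G0111", "G0113", "G0121", "G0126", "G0132", "G0141", "G0149", "G0153", "G0155", "G0166", "G0176", "G0204", "G0207", "G0209", "G0210", "G0241", "G0244", "G0251", "G0254", "G0262", "G0290", "G0301", "G0303", "G0312", "G0318", "G0319", "G0344", "G0350", "G0352", "G0354", "G0356", "G0357", "G0362", "G0365", "G0370", "G0372", "G0375", "G0378", "G0379", "G0395", "G0402", "G0403", "G0458", "G0466", "G0470", "G0474", "G0475", "G0485", "G0497", "G0499"],
  "planted_target_map": {
    "hsa-miR-s0107": ["G0052", "G0132", "G0356", "G0126", "G0080", "G0149", "G0262", "G0370"],
    "hsa-miR-s0699": ["G0499", "G0485", "G0474", "G0354", "G0121", "G0096", "G0312", "G0395"],
    "hsa-miR-s0329": ["G0470", "G0370", "G0254", "G0017", "G0113", "G0485", "G0365", "G0007"],
    "hsa-miR-s0667": ["G0350", "G0499", "G0378", "G0365", "G0209", "G0303", "G0210", "G0241"],
    "hsa-miR-s0033": ["G0458", "G0470", "G0121", "G0370", "G0013", "G0372", "G0126", "G0176"],
    "hsa-miR-s0551": ["G0402", "G0365", "G0378", "G0403", "G0318", "G0155", "G0121", "G0356"],
    "hsa-miR-s0745": ["G0379", "G0319", "G0357", "G0085", "G0013", "G0155", "G0096", "G0032"],
    "hsa-miR-s0030": ["G0103", "G0379", "G0207", "G0319", "G0318", "G0458", "G0350", "G0032"],
    "hsa-miR-s0064": ["G0470", "G0013", "G0319", "G0354", "G0209", "G0485", "G0166", "G0241"],
    "hsa-miR-s0129": ["G0497", "G0121", "G0210", "G0370", "G0155", "G0485", "G0069", "G0141"],
    "hsa-miR-s0574": ["G0017", "G0312", "G0458", "G0103", "G0262", "G0403", "G0370", "G0395"],
    "hsa-miR-s0286": ["G0312", "G0497", "G0013", "G0303", "G0126", "G0357", "G0354", "G0085"],
    "hsa-miR-s0336": ["G0395", "G0141", "G0207", "G0475", "G0069", "G0251", "G0497", "G0204"],
    "hsa-miR-s0750": ["G0103", "G0149", "G0354", "G0499", "G0352", "G0155", "G0126", "G0356"],
    "hsa-miR-s0270": ["G0149", "G0319", "G0365", "G0069", "G0166", "G0052", "G0466", "G0402"],
    "hsa-miR-s0095": ["G0155", "G0069", "G0080", "G0379", "G0132", "G0052", "G0485", "G0499"]
  },
  "gene_list_absent": ["FAKE01", "FAKE02", "FAKE03", "FAKE04"]
}
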