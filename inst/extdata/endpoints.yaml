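# Default immune health endpoint definitions.
# Each endpoint is a set of MeSH disease roots (expanded to all
# descendant terms) plus GO biological-process keywords.
endpoints:
  - name: hypersensitivity
    mesh_root_ids: ["MESH:D006967"]
    go_keywords: ["hypersensitivity", "allerg", "mast cell", "immunoglobulin e"]
  - name: autoimmunity
    mesh_root_ids: ["MESH:D001327"]
    go_keywords: ["autoimmun", "tolerance induction", "self antigen"]
  - name: infection
    # parasitic diseases (D010272; sometimes misprinted with an extra
    # digit), bacterial infections and mycoses (D001423), virus
    # diseases (D014777) merged into one endpoint
    mesh_root_ids: ["MESH:D010272", "MESH:D001423", "MESH:D014777"]
    go_keywords: ["defense response", "response to bacterium",
                  "response to virus", "antimicrobial"]
  - name: cancer
    mesh_root_ids: ["MESH:D009369"]
    go_keywords: ["tumor", "apoptotic", "cell cycle", "neoplas"]
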