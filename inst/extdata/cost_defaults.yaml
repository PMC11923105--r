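# Example per-component prices (USD) for the four genotyping workflows.
# These are illustrative placeholders, NOT authoritative reagent prices:
# edit them to your own vendor quotes before drawing cost conclusions.
# Structure is what matters: which components each workflow carries and
# whether they accrue per sample, per plate or per pooled run.
wells_per_plate: 96
workflows:
  conventional_sanger:
    components:
      - {name: DNA_prep, basis: per_sample, unit_cost: 2.50}
      - {name: pcr_master_mix, basis: per_sample, unit_cost: 0.60}
      - {name: primers, basis: per_plate, unit_cost: 2.00}
      - {name: purification, basis: per_sample, unit_cost: 1.20}
      - {name: sanger_sequencing, basis: per_sample, unit_cost: 4.50}
  sanger_no_prep:
    components:
      - {name: pcr_master_mix, basis: per_sample, unit_cost: 0.60}
      - {name: primers, basis: per_plate, unit_cost: 2.00}
      - {name: purification, basis: per_sample, unit_cost: 1.20}
      - {name: sanger_sequencing, basis: per_sample, unit_cost: 4.50}
  conventional_illumina_two_step:
    components:
      - {name: DNA_prep, basis: per_sample, unit_cost: 2.50}
      - {name: pcr_master_mix, basis: per_sample, unit_cost: 1.20}
      - {name: indexing_primers, basis: per_sample, unit_cost: 0.80}
      - {name: purification, basis: per_sample, unit_cost: 1.20}
      - {name: sequencing, basis: per_pool, unit_cost: 120.00}
  custom_four_barcode:
    components:
      - {name: pcr_master_mix, basis: per_sample, unit_cost: 0.60}
      - {name: primers, basis: per_plate, unit_cost: 4.00}
      - {name: purification, basis: per_pool, unit_cost: 1.50}
      - {name: sequencing, basis: per_pool, unit_cost: 120.00}
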