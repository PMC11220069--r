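family,genus,species,morpho_group,life_cycle_phase,shape_class,ks_body,ks_spinose,ks_exothecal,size_metric,y_fraction,y_fraction_incl_process,cn_multiplier,fixed_cn,fixed_cl,fixed_spine_length,dimorphic_spinose_fraction,appendage_pg_per_appendage,appendage_default_count,appendage_fixed_total_pg,coccolith_thickness,umbellosphaera_cl_factor,source_note
Noelaerhabdaceae,Emiliania,huxleyi,,heterococcolith,PROLATE_SPHERE,0.02,,0.02,distal_shield_length,0.86,,2,,,,,,,,0.13,,single Ks for all morphotypes; recommended small-placolith value
Noelaerhabdaceae,Gephyrocapsa,,,heterococcolith,PROLATE_SPHERE,0.05,,0.02,distal_shield_length,0.70,,2,,,,,,,,,,placeholder Ks and y from literature; confirm before use
Calcidiscaceae,Calcidiscus,,,heterococcolith,PROLATE_SPHERE,0.08,,0.02,distal_shield_length,0.42,,2,,,,,,,,,,placeholder Ks from literature; y is the light-microscopy mean
Calcidiscaceae,Umbilicosphaera,,,heterococcolith,PROLATE_SPHERE,0.06,,0.02,distal_shield_length,0.60,,2,,,,,,,,,,placeholder Ks and y from literature; confirm before use
Calcidiscaceae,Oolithotus,,,heterococcolith,PROLATE_SPHERE,0.06,,0.02,distal_shield_length,0.55,,2,,,,,,,,,,placeholder Ks and y from literature; confirm before use
Helicosphaeraceae,Helicosphaera,,,heterococcolith,PROLATE_SPHERE,0.05,,0.02,distal_shield_length,0.51,,2,,,,,,,,,,placeholder Ks from literature; y is the light-microscopy mean
Calciosoleniaceae,Calciosolenia,,,heterococcolith,DOUBLE_CONE,0.007,,0.02,distal_shield_length,0.75,,2,,,,,,,,,,Ks back-calculated from 2.5 pg coccolith calcite at 5 um length; y placeholder
Rhabdosphaeraceae,Rhabdosphaera,clavigera,,heterococcolith,PROLATE_SPHERE,0.025,0.1,0.02,distal_shield_length,0.60,0.30,2,,,5,0.5,,,,,,body Ks modified from Acanthoica; spinose Ks placeholder; 50/50 dimorphism with 5 um spine fallback
Rhabdosphaeraceae,Acanthoica,,,heterococcolith,PROLATE_SPHERE,0.03,,0.02,distal_shield_length,0.56,,2,,,,,,,,,,placeholder Ks; y is the light-microscopy mean (n=6); polar-spine calcite unmodelled
Rhabdosphaeraceae,Discosphaera,tubifera,,heterococcolith,PROLATE_SPHERE,0.06,,0.02,trumpet_width,0.60,0.30,2,,,,,,,,,,placeholder Ks from literature; calcite uses trumpet width
Syracosphaeraceae,Syracosphaera,,pulchra group,heterococcolith,PROLATE_SPHERE,0.03,,0.02,distal_shield_length,0.65,,2,,,,,,,,,,robust inner wall and central structures
Syracosphaeraceae,Syracosphaera,,molischii group,heterococcolith,PROLATE_SPHERE,0.022,,0.02,distal_shield_length,0.75,,2,,,,,,,,,,well-developed rim without central boss or spine
Syracosphaeraceae,Syracosphaera,,nodosa group,heterococcolith,PROLATE_SPHERE,0.015,,0.02,distal_shield_length,0.75,,2,,,,,,,,,,small-coccolith value; no inner wall or central structure
Syracosphaeraceae,Syracosphaera,,,heterococcolith,PROLATE_SPHERE,0.02,,0.02,distal_shield_length,0.75,,2,,,,,,,,,,unidentified-to-species fallback; y follows the group values
Syracosphaeraceae,Michaelsarsia,,,heterococcolith,PROLATE_SPHERE,0.03,,0.02,distal_shield_length,0.65,,2,,,,,12.5,8,,,,body Ks adapted from Syracosphaera; 12.5 pg per appendage and default 8 appendages
Syracosphaeraceae,Ophiaster,,,heterococcolith,PROLATE_SPHERE,0.015,,0.02,distal_shield_length,0.75,,2,,,,,,,33,,,body Ks adapted from Syracosphaera; fixed 33 pg appendage total when arms present
Alisphaeraceae,Alisphaera,,,polycrater,PROLATE_SPHERE,0.02,,0.02,distal_shield_length,0.75,,2,400,0.8,,,,,,,,polycrater phase; fixed count 400 and length 0.8 um; Ks and y placeholders
Umbellosphaeraceae,Umbellosphaera,,,heterococcolith,PROLATE_SPHERE,0.06,,0.02,distal_shield_length,0.50,,3,,,,,,,,,0.7,placeholder Ks and y; count multiplier 3 and average-length factor 0.7 for pseudo-multilayer coccospheres
incertae sedis,Florisphaera,profunda,,nannolith,PROLATE_SPHERE,0.03,,0.02,distal_shield_length,0.10,,2,145,,,,,,,,,nannolith Ks; fixed count 145; cell is 10 percent of coccosphere volume
,,,,holococcolith,PROLATE_SPHERE,0.036,,0.02,distal_shield_length,0.80,,2,,,,,,,,,,holococcolithophore phase default
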