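# Condition -> superordinate category mapping (32 entries).
#
# Modelled on a structured laboratory protocol of fully standardized and
# semi-standardized activities; edit or extend to match your own protocol.
# The 12 default synthetic conditions are a subset of these identifiers.
lying_horizontal: lying
lying_on_side: lying
lying_prone: lying
lying_reading: lying
sitting_leaned_backwards: sitting
sitting_upright: sitting
sitting_desk_work: sitting
sitting_reading_newspaper: sitting
sitting_talking: sitting
standing: standing
standing_talking: standing
standing_leaning: standing
tidying_up: adl
hanging_out_laundry: adl
sweeping_floor: adl
setting_table: adl
washing_dishes: adl
shelving_books: adl
climbing_stairs: climbing_stairs
climbing_stairs_fast: climbing_stairs
descending_stairs: climbing_stairs
walking_3.2kmh: walking
walking_4.3kmh: walking
walking_5.5kmh: walking
walking_outdoor: walking
walking_with_bag: walking
jogging_8kmh: jogging
jogging_10kmh: jogging
jogging_outdoor: jogging
cycling: cycling
cycling_fast: cycling
cycling_outdoor: cycling
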