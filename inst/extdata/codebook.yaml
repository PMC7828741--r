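# Harmonization codebook for four open-streets intercept surveys.
#
# One block per city dialect. Each harmonized variable names the raw column
# and either a raw -> harmonized value map or a `kind`:
#   numeric         raw numeric value (optional `scale` multiplier)
#   age_years       raw age in completed years
#   birthdate       raw ISO date of birth; age derived at the observation date
#   likert5_health  raw 1..5 self-rated health (1 excellent, 2 good, 3-5 fair)
#   likert5_safety  raw 1..5 safety Likert (1-2 unsafe, 3 neither, 4-5 safe)
# A variable absent from a city block is unavailable in that survey and is
# harmonized as explicit missing, never imputed.
default_observation_date: "2018-06-03"
cities:
  bogota:
    sex: {column: sexo, map: {M: male, F: female}}
    age: {column: edad, kind: age_years}
    marital:
      column: estado_civil
      map: {soltero: single, viudo: single, divorciado: single,
            separado: single, casado: partner, union_libre: partner}
    education:
      column: nivel_educativo
      map: {primaria: primary, secundaria: secondary,
            universitaria_tecnica: college, posgrado: masters_plus}
    ses:
      column: estrato
      map: {"1": low, "2": low, "3": middle, "4": middle, "5": high, "6": high}
    car: {column: carro_hogar, map: {si: "yes", "no": "no"}}
    health: {column: salud_5pt, kind: likert5_health}
    weight_kg: {column: peso_kg, kind: numeric}
    height_m: {column: estatura_cm, kind: numeric, scale: 0.01}
    pa_program_min: {column: minutos_af_programa, kind: numeric}
    ltpa_moderate_min: {column: min_moderada_semana, kind: numeric}
    ltpa_vigorous_min: {column: min_vigorosa_semana, kind: numeric}
    transport_min: {column: min_transporte_semana, kind: numeric}
    activity:
      column: actividad_principal
      map: {bicicleta: cycling, patines: rollerblading, caminar: walking,
            correr: running, trotar: running, otra: other}
    time_h: {column: horas_programa, kind: numeric}
    frequency:
      column: frecuencia
      map: {cada_domingo: ge4_per_month, dos_tres_por_mes: two_three_per_month,
            una_por_mes: one_per_month, al_menos_una_al_ano: ge1_per_year}
    companion: {column: compania, map: {solo: alone, acompanado: accompanied}}
    safety: {column: seguridad_likert, kind: likert5_safety}
  mexico_city:
    sex: {column: sexo, map: {hombre: male, mujer: female}}
    age: {column: fecha_nacimiento, kind: birthdate}
    marital:
      column: estado_civil
      map: {soltero: single, viudo: single, divorciado: single,
            separado: single, casado: partner, union_libre: partner}
    education:
      column: escolaridad
      map: {primaria: primary, secundaria: secondary, licenciatura: college,
            posgrado: masters_plus}
    ses: {column: nse, map: {bajo: low, medio: middle, alto: high}}
    car: {column: auto_hogar, map: {si: "yes", "no": "no"}}
    weight_kg: {column: peso_kg, kind: numeric}
    height_m: {column: estatura_m, kind: numeric}
    pa_program_min: {column: minutos_af_programa, kind: numeric}
    ltpa_moderate_min: {column: min_moderada_tiempo_libre, kind: numeric}
    ltpa_vigorous_min: {column: min_vigorosa_tiempo_libre, kind: numeric}
    transport_min: {column: min_transporte, kind: numeric}
    activity:
      column: actividad
      map: {bici: cycling, patines: rollerblading, caminata: walking,
            correr: running, otra: other}
    time_h: {column: horas_programa, kind: numeric}
    frequency:
      column: frecuencia
      map: {cada_domingo: ge4_per_month, dos_tres_por_mes: two_three_per_month,
            una_por_mes: one_per_month, al_menos_una_al_ano: ge1_per_year}
    companion: {column: acompanado, map: {solo: alone, acompanado: accompanied}}
  santiago_cali:
    sex: {column: sexo, map: {M: male, F: female}}
    age: {column: fecha_nacimiento, kind: birthdate}
    marital:
      column: estado_civil
      map: {soltero: single, viudo: single, divorciado: single,
            separado: single, casado: partner, union_libre: partner}
    education:
      column: educacion
      map: {primaria: primary, secundaria: secondary, universitaria: college,
            postgrado: masters_plus}
    ses:
      column: estrato
      map: {"1": low, "2": low, "3": middle, "4": middle, "5": high, "6": high}
    car: {column: carro, map: {si: "yes", "no": "no"}}
    health: {column: salud, kind: likert5_health}
    weight_kg: {column: peso_kg, kind: numeric}
    height_m: {column: estatura_cm, kind: numeric, scale: 0.01}
    pa_program_min: {column: minutos_programa, kind: numeric}
    activity:
      column: actividad
      map: {bicicleta: cycling, patines: rollerblading, caminar: walking,
            correr: running, otra: other}
    time_h: {column: horas, kind: numeric}
    frequency:
      column: frecuencia
      map: {cada_domingo: ge4_per_month, dos_tres_por_mes: two_three_per_month,
            una_por_mes: one_per_month, al_menos_una_al_ano: ge1_per_year}
    companion: {column: compania, map: {solo: alone, acompanado: accompanied}}
    safety: {column: seguridad, kind: likert5_safety}
  santiago_chile:
    sex: {column: sexo, map: {hombre: male, mujer: female}}
    age: {column: fecha_nacimiento, kind: birthdate}
    education:
      column: educacion
      map: {basica: primary, media: secondary, superior: college,
            magister_o_mas: masters_plus}
    ses:
      column: gse
      map: {E: low, D: low, C3: middle, C2: middle, ABC1: high}
    health: {column: salud, kind: likert5_health}
    pa_program_min: {column: minutos_programa, kind: numeric}
    activity:
      column: actividad
      map: {bicicleta: cycling, patines: rollerblading, caminar: walking,
            correr: running, otra: other}
    time_h: {column: horas, kind: numeric}
    frequency:
      column: frecuencia
      map: {cada_domingo: ge4_per_month, dos_tres_por_mes: two_three_per_month,
            una_por_mes: one_per_month, al_menos_una_al_ano: ge1_per_year}
    safety: {column: seguridad, kind: likert5_safety}
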