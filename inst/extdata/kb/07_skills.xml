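<?xml version="1.0" encoding="UTF-8"?>
<aiml version="subset-1" language="es">
<topic name="skills" description="things the patient was especially good at">
  <category trigger="true" entry="true">
    <pattern>habilidades</pattern>
    <template><random><li>¿Es verdad que eras muy buena para <get name="habilidad"/>?</li><li>¿Te gustaría platicar sobre <get name="habilidad"/>?</li><li>¿Qué actividad se te daba muy bien?</li></random></template>
  </category>
  <category trigger="true">
    <pattern>habilidades *</pattern>
    <template><srai>habilidades</srai></template>
  </category>
  <category trigger="true">
    <pattern>* habilidades</pattern>
    <template><srai>habilidades</srai></template>
  </category>
  <category trigger="true">
    <pattern>* habilidades *</pattern>
    <template><srai>habilidades</srai></template>
  </category>
  <category>
    <pattern>sí</pattern>
    <template><random><li>¡Qué bien! ¿Quién te enseñó <get name="habilidad"/>?</li><li>¡Muy bien! ¿Me cuentas más de eso?</li></random></template>
  </category>
  <category>
    <pattern>sí *</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>* sí</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>si</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>si *</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>* si</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>no</pattern>
    <template><random><li>Está bien. ¿De qué otra cosa te gustaría platicar?</li><li>No hay problema. ¿Hay otro tema que te guste más?</li></random></template>
  </category>
  <category>
    <pattern>no *</pattern>
    <template><srai>no</srai></template>
  </category>
  <category fallback="true">
    <pattern>fallback</pattern>
    <template><random><li>Entiendo. ¿Me cuentas un poco más?</li><li>Ya veo. ¿Qué más recuerdas de eso?</li></random></template>
  </category>
</topic>
</aiml>
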